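#' Prior specification for the BITS/BUCP models
#'
#' The hierarchical prior places a normal prior on each phase intercept,
#' `beta[i,1] ~ N(mu[i], 1/beta_prec)`, a normal hyperprior on its mean,
#' `mu[i] ~ N(mu_mean, 1/mu_prec)`, uniform priors on the innovation SD and the
#' lag-1 autocorrelation, and (for the unknown change-point model) a
#' categorical prior over the admissible change points `{4, ..., T - 3}`.
#'
#' Defaults follow the deliberately weak specification used for outcome scales
#' centred near 5: `beta_prec = 1`, `mu_mean = 5`, `mu_prec = 0.05` (hyperprior
#' variance 20), `sigma ~ U(0.1, 5)`, `rho ~ U(-1, 1)`, uniform change-point
#' weights.
#'
#' @param beta_prec precision of the intercept prior (> 0).
#' @param mu_mean hyperprior mean for the intercept means.
#' @param mu_prec hyperprior precision (> 0).
#' @param sigma_low,sigma_high uniform bounds on the innovation SD
#'   (`0 < sigma_low < sigma_high`).
#' @param rho_low,rho_high uniform bounds on the autocorrelation, within
#'   `[-1, 1]`.
#' @param cp_weights `NULL` for uniform weights over the change-point support,
#'   or a nonnegative vector (one weight per support point, normalised
#'   internally).
#' @return an object of class `prior_spec`.
#' @examples
#' prior_spec()
#' prior_spec(mu_prec = 0.1)
#' @export
prior_spec <- function(beta_prec = 1, mu_mean = 5, mu_prec = 0.05,
                       sigma_low = 0.1, sigma_high = 5,
                       rho_low = -1, rho_high = 1,
                       cp_weights = NULL) {
  stopifnot(
    beta_prec > 0, mu_prec > 0,
    sigma_low > 0, sigma_high > sigma_low,
    rho_low >= -1, rho_high <= 1, rho_high > rho_low
  )
  if (!is.null(cp_weights)) {
    if (any(cp_weights < 0) || sum(cp_weights) <= 0) {
      stop("cp_weights must be nonnegative with positive sum", call. = FALSE)
    }
    cp_weights <- cp_weights / sum(cp_weights)
  }
  structure(
    list(
      beta_prec = beta_prec, mu_mean = mu_mean, mu_prec = mu_prec,
      sigma_low = sigma_low, sigma_high = sigma_high,
      rho_low = rho_low, rho_high = rho_high,
      cp_weights = cp_weights
    ),
    class = "prior_spec"
  )
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec>\n")
  cat(sprintf("  beta[i,1] ~ N(mu[i], prec %g); mu[i] ~ N(%g, prec %g)\n",
              x$beta_prec, x$mu_mean, x$mu_prec))
  cat(sprintf("  sigma ~ U(%g, %g); rho ~ U(%g, %g)\n",
              x$sigma_low, x$sigma_high, x$rho_low, x$rho_high))
  cat(sprintf("  CP ~ Categorical(%s)\n",
              if (is.null(x$cp_weights)) "uniform over {4..T-3}"
              else paste(signif(x$cp_weights, 3), collapse = " ")))
  invisible(x)
}

#' Serialize / deserialize a prior specification
#'
#' The flat JSON representation uses exactly the field names of
#' [prior_spec()].
#'
#' @param prior a [prior_spec()].
#' @param path file path.
#' @return `read_prior_spec` returns a [prior_spec()]; `write_prior_spec`
#'   returns `path` invisibly.
#' @export
write_prior_spec <- function(prior, path) {
  stopifnot(inherits(prior, "prior_spec"))
  jsonlite::write_json(unclass(prior), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_prior_spec
#' @export
read_prior_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(prior_spec))
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    stop("unknown prior fields: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  do.call(prior_spec, x)
}

#' Change-point support for a series of length `n_time`
#'
#' The change point (index of the last baseline-governed observation) may not
#' fall inside the first or last three time points, leaving the integer range
#' `4 .. n_time - 3`.
#'
#' @param n_time total series length T.
#' @return integer vector of admissible change points.
#' @export
cp_support <- function(n_time) {
  if (n_time < 7L) {
    stop("change point cannot happen during the first three or last three ",
         "time points; need T >= 7", call. = FALSE)
  }
  4:(n_time - 3L)
}

cp_prior_weights <- function(prior, n_time) {
  sup <- cp_support(n_time)
  w <- prior$cp_weights
  if (is.null(w)) w <- rep(1 / length(sup), length(sup))
  if (length(w) != length(sup)) {
    stop(sprintf("cp_weights has length %d but the support {4..%d} has %d points",
                 length(w), n_time - 3L, length(sup)), call. = FALSE)
  }
  w / sum(w)
}

#' A point in BITS/BUCP parameter space
#'
#' @param beta1,beta2 baseline and treatment phase intercepts.
#' @param mu1,mu2 intercept hypermeans.
#' @param sigma_eps innovation standard deviation (> 0).
#' @param rho lag-1 autocorrelation.
#' @param cp integer change point (last baseline index); `NULL` for BITS.
#' @return object of class `model_state`.
#' @examples
#' model_state(4.2, 2.8, sigma_eps = 0.6, rho = -0.2)
#' @export
model_state <- function(beta1, beta2, mu1 = beta1, mu2 = beta2,
                        sigma_eps = 1, rho = 0, cp = NULL) {
  stopifnot(is.numeric(beta1), is.numeric(beta2), sigma_eps > 0)
  if (!is.null(cp)) {
    cp <- as.integer(cp)
    stopifnot(length(cp) == 1L, cp >= 1L)
  }
  structure(
    list(beta1 = beta1, beta2 = beta2, mu1 = mu1, mu2 = mu2,
         sigma_eps = sigma_eps, rho = rho, cp = cp),
    class = "model_state"
  )
}

#' @export
print.model_state <- function(x, ...) {
  cat(sprintf(
    "<model_state> beta=(%.4g, %.4g) mu=(%.4g, %.4g) sigma=%.4g rho=%.4g%s\n",
    x$beta1, x$beta2, x$mu1, x$mu2, x$sigma_eps, x$rho,
    if (is.null(x$cp)) "" else sprintf(" CP=%d", x$cp)
  ))
  invisible(x)
}
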