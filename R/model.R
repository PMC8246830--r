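#' Phase-level expected value under the interrupted time-series model
#'
#' The mean model is intercept-only: every observation in phase p has expected
#' value equal to that phase's intercept, constant in time.
#'
#' @param state a [model_state()].
#' @param phase 1 (baseline) or 2 (treatment).
#' @return the phase intercept.
#' @export
predicted_mean_bits <- function(state, phase) {
  stopifnot(inherits(state, "model_state"))
  if (!phase %in% c(1, 2)) stop("phase must be 1 or 2", call. = FALSE)
  if (phase == 1) state$beta1 else state$beta2
}

#' Expected value at time t under the unknown change-point model
#'
#' The mean switches from the baseline to the treatment intercept after the
#' change point: observations with `t <= cp` take `beta1`, later ones `beta2`
#' (the change point is the index of the last baseline-governed observation).
#'
#' @param state a [model_state()] with `cp` set.
#' @param t integer time index in `1..n_time`.
#' @param n_time total series length T.
#' @return the step-function mean at time t.
#' @export
predicted_mean_bucp <- function(state, t, n_time) {
  stopifnot(inherits(state, "model_state"))
  if (is.null(state$cp)) stop("state has no change point", call. = FALSE)
  if (any(t < 1 | t > n_time)) {
    stop(sprintf("time index out of range 1..%d", n_time), call. = FALSE)
  }
  ifelse(t <= state$cp, state$beta1, state$beta2)
}

# Log-likelihood of one phase under an AR(1)-error intercept model whose
# conditioning restarts at the phase start: the first observation is
# unconditional with SD sigma, later ones condition on the previous residual.
ar1_phase_loglik <- function(y, b, sigma, rho) {
  n <- length(y)
  ll <- stats::dnorm(y[1], b, sigma, log = TRUE)
  if (n > 1L) {
    ll <- ll + sum(stats::dnorm(
      y[-1], b + rho * (y[-n] - b), sigma, log = TRUE
    ))
  }
  ll
}

#' BITS log-likelihood
#'
#' Each phase is an independent AR(1)-error chain around its own intercept:
#' the first observation of each phase is `N(beta_p, sigma_eps^2)`, and for
#' `t >= 2` the observation is normal around
#' `beta_p + rho * (y[t-1] - beta_p)` with SD `sigma_eps`. The autoregressive
#' conditioning restarts at the phase boundary.
#'
#' @param series an [sced_series()].
#' @param state a [model_state()]; any change point is ignored.
#' @return the log-likelihood (a scalar).
#' @export
bits_loglik <- function(series, state) {
  stopifnot(inherits(series, "sced_series"), inherits(state, "model_state"))
  if (state$sigma_eps <= 0) stop("sigma_eps must be > 0", call. = FALSE)
  ar1_phase_loglik(series$baseline, state$beta1, state$sigma_eps, state$rho) +
    ar1_phase_loglik(series$treatment, state$beta2, state$sigma_eps, state$rho)
}

#' BUCP log-likelihood
#'
#' A single unbroken AR(1) chain over the concatenated series with a
#' step-function mean: observations up to the change point take the baseline
#' intercept, later ones the treatment intercept. Only the very first
#' observation is unconditional; in particular the conditioning does not
#' restart at the change point, so the first post-change observation is
#' conditioned on the last pre-change one.
#'
#' @param series an [sced_series()].
#' @param state a [model_state()] with `cp` set.
#' @return the log-likelihood (a scalar).
#' @export
bucp_loglik <- function(series, state) {
  stopifnot(inherits(series, "sced_series"), inherits(state, "model_state"))
  if (is.null(state$cp)) stop("state has no change point", call. = FALSE)
  if (state$sigma_eps <= 0) stop("sigma_eps must be > 0", call. = FALSE)
  y <- series_values(series)
  n <- length(y)
  m <- ifelse(seq_len(n) <= state$cp, state$beta1, state$beta2)
  ll <- stats::dnorm(y[1], m[1], state$sigma_eps, log = TRUE)
  ll + sum(stats::dnorm(
    y[-1], m[-1] + state$rho * (y[-n] - m[-n]), state$sigma_eps, log = TRUE
  ))
}

#' Joint log-prior density of a model state
#'
#' Sums the log-densities of the hierarchical prior (see [prior_spec()]):
#' normal intercepts given their hypermeans, normal hypermeans, uniform
#' innovation SD and autocorrelation, and -- for `model = "bucp"` -- the
#' categorical change-point prior. States outside the support return `-Inf`
#' rather than raising, so a Metropolis step can simply reject them.
#'
#' @param state a [model_state()].
#' @param prior a [prior_spec()].
#' @param model `"bits"` or `"bucp"`.
#' @param n_time total series length, required for the BUCP change-point term.
#' @return log prior density, possibly `-Inf`.
#' @export
log_prior <- function(state, prior, model = c("bits", "bucp"), n_time = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(state, "model_state"), inherits(prior, "prior_spec"))
  if (state$sigma_eps <= prior$sigma_low || state$sigma_eps >= prior$sigma_high)
    return(-Inf)
  if (state$rho <= prior$rho_low || state$rho >= prior$rho_high)
    return(-Inf)
  lp <-
    stats::dnorm(state$beta1, state$mu1, 1 / sqrt(prior$beta_prec), log = TRUE) +
    stats::dnorm(state$beta2, state$mu2, 1 / sqrt(prior$beta_prec), log = TRUE) +
    stats::dnorm(state$mu1, prior$mu_mean, 1 / sqrt(prior$mu_prec), log = TRUE) +
    stats::dnorm(state$mu2, prior$mu_mean, 1 / sqrt(prior$mu_prec), log = TRUE) -
    log(prior$sigma_high - prior$sigma_low) -
    log(prior$rho_high - prior$rho_low)
  if (model == "bucp") {
    if (is.null(state$cp)) stop("bucp state needs a change point", call. = FALSE)
    if (is.null(n_time)) stop("n_time is required for model = 'bucp'", call. = FALSE)
    sup <- cp_support(n_time)
    if (!state$cp %in% sup) return(-Inf)
    w <- cp_prior_weights(prior, n_time)
    wi <- w[match(state$cp, sup)]
    if (wi <= 0) return(-Inf)
    lp <- lp + log(wi)
  }
  lp
}

#' White-noise SD implied by an AR(1) process
#'
#' Converts the innovation SD `sigma_eps` and lag-1 autocorrelation `rho` into
#' the white-noise SD `sigma_eps * sqrt(1 - rho^2)`. This is a reporting
#' utility; it plays no role in the likelihood.
#'
#' @param sigma_eps innovation SD (> 0).
#' @param rho lag-1 autocorrelation, `|rho| < 1`.
#' @return the white-noise SD.
#' @examples
#' white_noise_sd(1, 0.6) # 0.8
#' @export
white_noise_sd <- function(sigma_eps, rho) {
  stopifnot(sigma_eps > 0)
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1", call. = FALSE)
  sigma_eps * sqrt(1 - rho^2)
}

#' Standardized mean difference effect size
#'
#' `(beta1 - beta2) / sigma_eps`: positive when the baseline level exceeds the
#' treatment level, i.e. when a symptom-type outcome decreases under
#' treatment. Computed draw-wise over the posterior this yields the effect
#' size posterior, which carries its own small-sample uncertainty and needs no
#' external correction factor.
#'
#' @param state a [model_state()].
#' @return the effect size.
#' @examples
#' effect_size(model_state(3, 1, sigma_eps = 1)) # 2
#' @export
effect_size <- function(state) {
  stopifnot(inherits(state, "model_state"))
  if (state$sigma_eps <= 0) stop("sigma_eps must be > 0", call. = FALSE)
  (state$beta1 - state$beta2) / state$sigma_eps
}

#' Immediacy of the treatment effect
#'
#' The difference between the median of the last three baseline observations
#' and the median of the first three treatment observations. There is no
#' accepted rule of thumb for interpreting its magnitude; it complements the
#' change-point posterior as descriptive evidence of an immediate effect.
#'
#' @param series an [sced_series()].
#' @return the immediacy statistic.
#' @examples
#' immediacy(suppressWarnings(sced_p7())) # 1.01
#' @export
immediacy <- function(series) {
  stopifnot(inherits(series, "sced_series"))
  b <- series$baseline
  tr <- series$treatment
  if (length(b) < 3L || length(tr) < 3L) {
    stop("immediacy needs at least three observations per phase", call. = FALSE)
  }
  stats::median(b[(length(b) - 2L):length(b)]) - stats::median(tr[1:3])
}
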