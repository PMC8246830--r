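#' Univariate potential scale reduction factor
#'
#' Gelman-Rubin shrink factor for one parameter sampled by `m >= 2` chains of
#' equal length `n`: with `W` the mean within-chain variance and `B/n` the
#' variance of the chain means,
#' `Rhat = sqrt(((n - 1)/n * W + B/n) / W)`. Values near 1 indicate the
#' chains are mixing over the same distribution.
#'
#' @param chains list of equal-length numeric vectors (one per chain), or a
#'   matrix with one column per chain.
#' @return the scalar PSRF.
#' @export
psrf <- function(chains) {
  chains <- as_chain_list(chains)
  m <- length(chains)
  if (m < 2L) stop("psrf needs at least 2 chains", call. = FALSE)
  n <- length(chains[[1]])
  if (n < 10L) stop("psrf needs at least 10 draws per chain", call. = FALSE)
  W <- mean(vapply(chains, stats::var, numeric(1)))
  Bn <- stats::var(vapply(chains, mean, numeric(1)))
  sqrt(((n - 1) / n * W + Bn) / W)
}

as_chain_list <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (!is.list(chains)) stop("chains must be a list or a matrix", call. = FALSE)
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("all chains must have equal length", call. = FALSE)
  lapply(chains, as.numeric)
}

#' Multivariate potential scale reduction factor
#'
#' Brooks-Gelman multivariate shrink factor over all monitored continuous
#' parameters: `Rp = (n - 1)/n + ((m + 1)/m) * lambda1`, with `lambda1` the
#' largest eigenvalue of `W^{-1} B/n`, `W` the pooled within-chain covariance
#' and `B/n` the between-chain covariance of the chain mean vectors. It bounds
#' the squared univariate factors of every linear combination of the
#' parameters (up to the `(m + 1)/m` inflation).
#'
#' @param chains list of `n x p` matrices (one per chain, equal dimensions,
#'   same column order).
#' @return the scalar MPSRF (on the squared-PSRF scale).
#' @export
mpsrf <- function(chains) {
  if (!is.list(chains) || !all(vapply(chains, is.matrix, logical(1)))) {
    stop("chains must be a list of matrices", call. = FALSE)
  }
  m <- length(chains)
  if (m < 2L) stop("mpsrf needs at least 2 chains", call. = FALSE)
  n <- nrow(chains[[1]])
  W <- Reduce(`+`, lapply(chains, stats::cov)) / m
  means <- do.call(rbind, lapply(chains, colMeans))
  Bn <- stats::cov(means)
  WinvB <- tryCatch(solve(W, Bn), error = function(e) {
    stop("within-chain covariance is singular; exclude degenerate or ",
         "discrete parameters (e.g. CP) from the MPSRF computation",
         call. = FALSE)
  })
  lambda1 <- max(Re(eigen(WinvB, only.values = TRUE)$values))
  (n - 1) / n + (m + 1) / m * lambda1
}

#' Spectral density at frequency zero of a chain
#'
#' Estimated by fitting an autoregressive approximation (order chosen by AIC,
#' capped at `order_max`): `S(0) = var_pred / (1 - sum(ar_coefs))^2`. For an
#' iid chain this reduces to the sample variance. A constant chain returns 0.
#'
#' @param x numeric vector (one chain of one parameter).
#' @param order_max maximum AR order considered.
#' @return estimated spectral density at zero.
#' @export
spectrum0_ar <- function(x, order_max = 10L) {
  x <- as.numeric(x)
  if (stats::sd(x) == 0) return(0)
  order_max <- min(order_max, length(x) - 1L)
  fit <- stats::ar(x, aic = TRUE, order.max = order_max)
  fit$var.pred / (1 - sum(fit$ar))^2
}

# Asymptotic CDF of the Cramer-von Mises statistic, evaluated by the standard
# Bessel-function series. The four-term series is accurate in the quantile
# range that matters (0.90/0.95/0.99 at 0.347/0.461/0.743) but decays
# spuriously for very large q, so the tail is clamped to 1 there.
pcramer <- function(q, eps = 1e-5) {
  if (q >= 3) return(1)
  log.eps <- log(eps)
  y <- 0
  for (k in 0:3) {
    z <- gamma(k + 0.5) * sqrt(4 * k + 1) / (gamma(k + 1) * pi^1.5 * sqrt(q))
    u <- (4 * k + 1)^2 / (16 * q)
    if (u > -log.eps) next
    y <- y + z * exp(-u) * besselK(x = u, nu = 0.25)
  }
  min(y, 1)
}

#' Heidelberger-Welch convergence diagnostic for one chain
#'
#' Stationarity: a Cramer-von Mises test on the standardized cumulative-sum
#' (Brownian bridge) process of the chain, with the long-run variance
#' estimated by [spectrum0_ar()] on the second half of the chain. If the test
#' rejects at `alpha`, the initial 10% of the chain is discarded and the test
#' repeated, up to a maximum of 50% discarded; failure at every fraction fails
#' the diagnostic. Halfwidth: on the retained portion, the test passes when
#' `z[1 - alpha/2] * sqrt(S(0)/n)` is at most `eps` times the absolute mean.
#'
#' A constant chain passes both parts trivially (halfwidth 0).
#'
#' @param x numeric vector, one chain of one parameter (>= 100 draws).
#' @param alpha stationarity test level and halfwidth confidence complement.
#' @param eps halfwidth tolerance relative to the mean.
#' @return list with `stationarity` (`"pass"`/`"fail"`), `frac_discarded`,
#'   `n_kept`, `mean`, `halfwidth`, `rel_halfwidth`, `halfwidth_test`.
#' @export
heidelberger_welch <- function(x, alpha = 0.05, eps = 0.1) {
  x <- as.numeric(x)
  n0 <- length(x)
  if (n0 < 100L) stop("heidelberger_welch needs at least 100 draws", call. = FALSE)
  if (stats::sd(x) == 0) {
    return(list(stationarity = "pass", frac_discarded = 0, n_kept = n0,
                mean = x[1], halfwidth = 0, rel_halfwidth = 0,
                halfwidth_test = "pass"))
  }
  S0 <- spectrum0_ar(x[seq.int(floor(n0 / 2) + 1L, n0)])
  fracs <- seq(0, 0.5, by = 0.1)
  converged <- FALSE
  kept <- x
  frac <- 0.5
  for (f in fracs) {
    kept <- x[seq.int(floor(f * n0) + 1L, n0)]
    n <- length(kept)
    ybar <- mean(kept)
    B <- cumsum(kept) - ybar * seq_len(n)
    cvm <- sum((B * B) / (n * S0)) / n
    if (is.finite(cvm) && pcramer(cvm) < 1 - alpha) {
      converged <- TRUE
      frac <- f
      break
    }
  }
  n <- length(kept)
  S0k <- spectrum0_ar(kept)
  hw <- stats::qnorm(1 - alpha / 2) * sqrt(S0k / n)
  rel <- abs(hw / mean(kept))
  list(
    stationarity = if (converged) "pass" else "fail",
    frac_discarded = frac,
    n_kept = n,
    mean = mean(kept),
    halfwidth = hw,
    rel_halfwidth = rel,
    halfwidth_test = if (is.finite(rel) && rel <= eps) "pass" else "fail"
  )
}

#' Convergence report for a fitted model
#'
#' Computes the univariate PSRF for every monitored parameter, the MPSRF over
#' the continuous parameters, and per-parameter Heidelberger-Welch results on
#' the pooled-per-chain draws (worst chain reported). The integer change point
#' is excluded from the PSRF/MPSRF covariance computation (discreteness breaks
#' the normal-theory assumptions) and assessed instead by the maximum
#' total-variation distance between the per-chain CP frequency tables.
#'
#' A fit is flagged `converged` when all PSRFs and the MPSRF are below
#' `threshold` and, for BUCP, the CP total-variation distance is below 0.05.
#' The threshold is reported, never enforced.
#'
#' @param samples a [fit_sced()] result.
#' @param threshold PSRF/MPSRF flag threshold.
#' @param alpha,eps Heidelberger-Welch settings.
#' @return object of class `convergence_report`: list with `psrf`, `mpsrf`,
#'   `hw` (per parameter, worst chain), `cp_tv` (BUCP only), `converged`.
#' @export
convergence_report <- function(samples, threshold = 1.1, alpha = 0.05,
                               eps = 0.1) {
  stopifnot(inherits(samples, "sced_posterior"))
  pars <- colnames(samples$draws[[1]])
  cont <- setdiff(pars, "CP")
  psrf_v <- vapply(cont, function(p) {
    psrf(lapply(samples$draws, function(m) m[, p]))
  }, numeric(1))
  mp <- mpsrf(lapply(samples$draws, function(m) m[, cont, drop = FALSE]))
  hw <- lapply(cont, function(p) {
    per_chain <- lapply(samples$draws, function(m) {
      heidelberger_welch(m[, p], alpha = alpha, eps = eps)
    })
    worst <- which.max(vapply(per_chain, function(h) {
      (h$stationarity == "fail") * 10 + h$frac_discarded
    }, numeric(1)))
    per_chain[[worst]]
  })
  names(hw) <- cont
  cp_tv <- NULL
  if ("CP" %in% pars) {
    sup <- cp_support(phase_lengths(samples$series)$T)
    tabs <- lapply(samples$draws, function(m) {
      tabulate(match(m[, "CP"], sup), nbins = length(sup)) / nrow(m)
    })
    ref <- Reduce(`+`, tabs) / length(tabs)
    cp_tv <- max(vapply(tabs, function(p) sum(abs(p - ref)) / 2, numeric(1)))
  }
  conv <- all(psrf_v < threshold) && mp < threshold &&
    (is.null(cp_tv) || cp_tv < 0.05)
  structure(
    list(psrf = psrf_v, mpsrf = mp, hw = hw, cp_tv = cp_tv,
         threshold = threshold, converged = conv),
    class = "convergence_report"
  )
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("<convergence_report>\n")
  cat("  PSRF: ", paste(sprintf("%s=%.3f", names(x$psrf), x$psrf),
                        collapse = " "), "\n")
  cat(sprintf("  MPSRF: %.3f (threshold %.2f)\n", x$mpsrf, x$threshold))
  if (!is.null(x$cp_tv)) cat(sprintf("  CP between-chain TV distance: %.4f\n", x$cp_tv))
  st <- vapply(x$hw, `[[`, character(1), "stationarity")
  hwt <- vapply(x$hw, `[[`, character(1), "halfwidth_test")
  cat("  Heidelberger-Welch stationarity:",
      sum(st == "pass"), "of", length(st), "pass\n")
  cat("  Heidelberger-Welch halfwidth:   ",
      sum(hwt == "pass"), "of", length(hwt), "pass\n")
  cat("  converged:", x$converged, "\n")
  invisible(x)
}

#' Serialize a convergence report to JSON
#'
#' @param report a [convergence_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_convergence_json <- function(report, path) {
  stopifnot(inherits(report, "convergence_report"))
  out <- unclass(report)
  out$psrf <- as.list(out$psrf) # keep parameter names in the JSON object
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}
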