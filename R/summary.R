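table_order <- function(model) {
  core <- c("beta[1,1]", "beta[2,1]", "sigma", "rho", "es")
  if (model == "bucp") c("CP", core) else core
}

#' Posterior summary table
#'
#' Pools all chains and reports, per parameter, the bounds of a 95% interval,
#' the median, the mean and the SD (denominator `n - 1`), in the canonical
#' reporting order: change point first (BUCP only), then the two intercepts,
#' `sigma`, `rho` and the effect size. Quantiles use linear interpolation
#' between order statistics (R's type-7 rule).
#'
#' @param samples a [fit_sced()] result.
#' @param interval `"equal_tailed"` (2.5% and 97.5% quantiles) or `"hdi"`
#'   (95% highest-density interval bounds).
#' @param parameters parameters to summarize; defaults to the reporting set.
#'   Requesting an unknown parameter is an error.
#' @param mass interval mass.
#' @return a `data.frame` of class `sced_summary` with columns
#'   `parameter,lower95,median,upper95,mean,sd`.
#' @export
summarize_posterior <- function(samples,
                                interval = c("equal_tailed", "hdi"),
                                parameters = NULL, mass = 0.95) {
  stopifnot(inherits(samples, "sced_posterior"))
  interval <- match.arg(interval)
  pars <- parameters %||% table_order(samples$model)
  known <- colnames(samples$draws[[1]])
  if (!all(pars %in% known)) {
    stop("unknown parameter(s): ",
         paste(setdiff(pars, known), collapse = ", "), call. = FALSE)
  }
  rows <- lapply(pars, function(p) {
    d <- pooled_draws(samples, p)
    if (interval == "equal_tailed") {
      q <- stats::quantile(d, c((1 - mass) / 2, 0.5, 1 - (1 - mass) / 2),
                           names = FALSE, type = 7)
      lo <- q[1]; md <- q[2]; hi <- q[3]
    } else {
      h <- hdi(d, mass = mass)
      lo <- h[1]; hi <- h[2]
      md <- stats::median(d)
    }
    data.frame(parameter = p, lower95 = lo, median = md, upper95 = hi,
               mean = mean(d), sd = stats::sd(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sced_summary", "data.frame")
  attr(out, "interval") <- interval
  out
}

#' @export
print.sced_summary <- function(x, ...) {
  y <- x
  class(y) <- "data.frame"
  for (j in c("lower95", "median", "upper95", "mean", "sd")) {
    y[[j]] <- signif(y[[j]], 4)
  }
  print(y, row.names = FALSE)
  invisible(x)
}

#' Highest-density interval of a sample
#'
#' The narrowest contiguous window of `ceiling(mass * n)` sorted draws. For a
#' symmetric unimodal posterior this approximately matches the equal-tailed
#' interval; for skewed posteriors it is strictly narrower.
#'
#' @param draws numeric vector (n >= 10).
#' @param mass interval mass in (0, 1).
#' @return numeric vector `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  draws <- as.numeric(draws)
  n <- length(draws)
  if (n < 10L) stop("hdi needs at least 10 draws", call. = FALSE)
  s <- sort(draws)
  k <- ceiling(mass * n)
  widths <- s[k:n] - s[1:(n - k + 1L)]
  i <- which.min(widths)
  c(s[i], s[i + k - 1L])
}

#' Fraction of effect-size draws beyond a practical threshold
#'
#' Reports the posterior probability that the effect size exceeds
#' `comp_val - rope_rad`, the smallest effect the analyst would accept as
#' practically meaningful (the lower edge of the region of practical
#' equivalence around the comparison value).
#'
#' @param draws posterior draws (typically the pooled `es` draws).
#' @param comp_val comparison value.
#' @param rope_rad nonnegative ROPE radius.
#' @return fraction of draws strictly greater than `comp_val - rope_rad`.
#' @export
rope_fraction <- function(draws, comp_val = 1, rope_rad = 0.5) {
  if (rope_rad < 0) stop("rope_rad must be >= 0", call. = FALSE)
  mean(as.numeric(draws) > comp_val - rope_rad)
}

#' Change-point posterior mode and probability table
#'
#' @param samples a [fit_sced()] result for a BUCP fit.
#' @return list with `mode` (ties broken toward the smaller change point) and
#'   `table` (named, normalized frequency over the support).
#' @export
cp_mode_and_table <- function(samples) {
  stopifnot(inherits(samples, "sced_posterior"))
  if (samples$model != "bucp") {
    stop("change-point summaries require a BUCP fit", call. = FALSE)
  }
  sup <- cp_support(phase_lengths(samples$series)$T)
  d <- pooled_draws(samples, "CP")
  tab <- tabulate(match(d, sup), nbins = length(sup)) / length(d)
  names(tab) <- sup
  list(mode = sup[which.max(tab)], table = tab)
}

#' Monte-Carlo standard error of a posterior mean
#'
#' Chain-aware batch estimate: the MCSE of each chain's mean from its
#' spectral density at zero, combined across independent chains.
#'
#' @param samples a [fit_sced()] result.
#' @param parameter parameter name.
#' @return estimated standard error of the pooled posterior mean.
#' @export
mcse_mean <- function(samples, parameter) {
  stopifnot(inherits(samples, "sced_posterior"))
  per <- vapply(samples$draws, function(m) {
    spectrum0_ar(m[, parameter]) / nrow(m)
  }, numeric(1))
  sqrt(mean(per) / length(per))
}
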