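open_device <- function(path, width, height) {
  if (is.null(path) || !nzchar(path)) stop("empty plot path", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = grDevices::png(path, width = width, height = height, res = 110),
    jpg = ,
    jpeg = grDevices::jpeg(path, width = width, height = height, res = 110),
    pdf = grDevices::pdf(path, width = width / 110, height = height / 110),
    stop(sprintf("unsupported plot format '.%s' (use png, jpg or pdf)", ext),
         call. = FALSE)
  )
}

#' Single-case design plot
#'
#' Line-and-marker plot of the outcome against time with a vertical divider
#' between the last baseline and first treatment observation.
#'
#' @param series an [sced_series()].
#' @param path output file (`.png`, `.jpg` or `.pdf`); `NULL` draws on the
#'   current device.
#' @return `path`, invisibly.
#' @export
plot_ssd <- function(series, path = NULL) {
  stopifnot(inherits(series, "sced_series"))
  if (!is.null(path)) {
    open_device(path, 800, 500)
    on.exit(grDevices::dev.off())
  }
  y <- series_values(series)
  tb <- length(series$baseline)
  plot(seq_along(y), y, type = "b", pch = 19, xlab = "Time",
       ylab = series$outcome_name,
       main = sprintf("Participant %s", series$participant_id))
  graphics::abline(v = tb + 0.5, lty = 2)
  graphics::mtext("baseline", side = 3, at = (1 + tb) / 2, line = -1.2, cex = 0.8)
  graphics::mtext("treatment", side = 3, at = tb + (1 + length(series$treatment)) / 2,
                  line = -1.2, cex = 0.8)
  invisible(path)
}

#' Trace plots and histograms of the posterior
#'
#' One row per monitored parameter: a trace (one line per chain) and a
#' histogram of the pooled draws. The change point is drawn with integer bins.
#'
#' @param samples a [fit_sced()] result.
#' @param path output file; `NULL` draws on the current device.
#' @param parameters subset of parameters (default: the reporting set).
#' @param max_trace at most this many iterations are drawn per trace (thinned
#'   uniformly) to keep files small.
#' @return `path`, invisibly.
#' @export
plot_posteriors <- function(samples, path = NULL, parameters = NULL,
                            max_trace = 2000) {
  stopifnot(inherits(samples, "sced_posterior"))
  pars <- parameters %||% table_order(samples$model)
  if (!is.null(path)) {
    open_device(path, 900, 220 * length(pars))
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(length(pars), 2),
                      mar = c(3.5, 3.5, 2, 0.5), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(op), add = TRUE)
  n <- nrow(samples$draws[[1]])
  idx <- if (n > max_trace) round(seq(1, n, length.out = max_trace)) else seq_len(n)
  for (p in pars) {
    chains <- lapply(samples$draws, function(m) m[, p])
    rng <- range(unlist(chains))
    plot(NULL, xlim = c(1, n), ylim = rng, xlab = "Iteration", ylab = p,
         main = sprintf("Trace: %s", p))
    for (ch in seq_along(chains)) {
      graphics::lines(idx, chains[[ch]][idx], col = ch)
    }
    pooled <- unlist(chains)
    if (p == "CP") {
      sup <- cp_support(phase_lengths(samples$series)$T)
      graphics::hist(pooled, breaks = c(sup - 0.5, max(sup) + 0.5),
                     freq = FALSE, xlab = p, main = sprintf("Posterior: %s", p))
    } else {
      graphics::hist(pooled, breaks = 60, freq = FALSE, xlab = p,
                     main = sprintf("Posterior: %s", p))
    }
  }
  invisible(path)
}

#' Effect-size posterior with ROPE annotation
#'
#' Histogram of the effect-size draws, a vertical line at the practical
#' threshold `comp_val - rope_rad`, the percentage of draws above it, and the
#' bounds of the highest-density interval.
#'
#' @param es_draws numeric vector of effect-size draws.
#' @param comp_val comparison value.
#' @param rope_rad ROPE radius.
#' @param hdi_mass HDI mass.
#' @param path output file; `NULL` draws on the current device.
#' @return list with `threshold`, `fraction`, `hdi`, invisibly.
#' @export
plot_rope <- function(es_draws, comp_val = 1, rope_rad = 0.5,
                      hdi_mass = 0.95, path = NULL) {
  es_draws <- as.numeric(es_draws)
  if (!length(es_draws)) stop("no effect-size draws", call. = FALSE)
  thr <- comp_val - rope_rad
  frac <- rope_fraction(es_draws, comp_val, rope_rad)
  h <- hdi(es_draws, mass = hdi_mass)
  if (!is.null(path)) {
    open_device(path, 800, 500)
    on.exit(grDevices::dev.off())
  }
  graphics::hist(es_draws, breaks = 60, freq = FALSE, xlab = "Effect size",
                 main = "Effect size posterior and ROPE")
  graphics::abline(v = thr, lwd = 2, lty = 2, col = "red")
  graphics::segments(h[1], 0, h[2], 0, lwd = 4, col = "blue")
  graphics::legend("topright", bty = "n", legend = c(
    sprintf("%.0f%% of draws > %.2f", 100 * frac, thr),
    sprintf("%d%% HDI [%.2f, %.2f]", round(100 * hdi_mass), h[1], h[2])
  ))
  invisible(list(threshold = thr, fraction = frac, hdi = h))
}
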