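#' Construct a two-phase single-case series
#'
#' An `sced_series` holds the repeated measurements of one continuous outcome
#' for one participant across a baseline (A) phase and a treatment (B) phase.
#' Time is indexed 1..T with the baseline first, so observation `t` of the
#' treatment phase sits at overall time `T_b + t`.
#'
#' Both phases must contain at least three finite observations (the What Works
#' Clearinghouse minimum for discerning a pattern). A warning is raised when
#' either phase has fewer than eight points, the length below which interval
#' estimates from these models become noticeably diffuse.
#'
#' @param baseline numeric vector of baseline-phase outcomes, in time order.
#' @param treatment numeric vector of treatment-phase outcomes, in time order.
#' @param participant_id single string identifying the case.
#' @param outcome_name single string naming the outcome scale.
#' @return An object of class `sced_series` with fields `participant_id`,
#'   `baseline`, `treatment`, `outcome_name`.
#' @examples
#' s <- suppressWarnings(sced_series(c(5, 4, 5, 6), c(2, 3, 2, 1), "S1"))
#' length(s$baseline)
#' @export
sced_series <- function(baseline, treatment, participant_id = "P1",
                        outcome_name = "outcome") {
  baseline <- as.numeric(baseline)
  treatment <- as.numeric(treatment)
  baseline <- baseline[!is.na(baseline)]
  treatment <- treatment[!is.na(treatment)]
  if (!all(is.finite(baseline)) || !all(is.finite(treatment))) {
    stop("all observations must be finite", call. = FALSE)
  }
  if (length(baseline) < 3L || length(treatment) < 3L) {
    stop(sprintf(
      "each phase needs at least 3 observations (got baseline=%d, treatment=%d) for participant '%s'",
      length(baseline), length(treatment), participant_id
    ), call. = FALSE)
  }
  if (length(baseline) < 8L || length(treatment) < 8L) {
    warning(sprintf(
      "participant '%s': phases have %d/%d points; fewer than 8 per phase gives diffuse estimates",
      participant_id, length(baseline), length(treatment)
    ), call. = FALSE)
  }
  structure(
    list(
      participant_id = as.character(participant_id)[1],
      baseline = baseline,
      treatment = treatment,
      outcome_name = as.character(outcome_name)[1]
    ),
    class = "sced_series"
  )
}

#' @export
print.sced_series <- function(x, ...) {
  cat(sprintf(
    "<sced_series> participant %s, outcome '%s': T_b=%d, T_t=%d\n",
    x$participant_id, x$outcome_name, length(x$baseline), length(x$treatment)
  ))
  cat("  baseline: ", paste(format(x$baseline), collapse = " "), "\n")
  cat("  treatment:", paste(format(x$treatment), collapse = " "), "\n")
  invisible(x)
}

#' Number of observations in a series
#' @param series an [sced_series()].
#' @return list with `T_b`, `T_t` and total `T`.
#' @export
phase_lengths <- function(series) {
  stopifnot(inherits(series, "sced_series"))
  tb <- length(series$baseline)
  tt <- length(series$treatment)
  list(T_b = tb, T_t = tt, T = tb + tt)
}

#' Concatenated outcome vector, baseline first
#' @param series an [sced_series()].
#' @return numeric vector of length `T_b + T_t`.
#' @export
series_values <- function(series) {
  stopifnot(inherits(series, "sced_series"))
  c(series$baseline, series$treatment)
}

#' The worked-example self-blame series (participant P7)
#'
#' Six weekly baseline and six weekly treatment measurements of the
#' Posttraumatic Cognitions Inventory Self-Blame subscale (range 1-7) for one
#' trauma-exposed adult who received a brief compassion-based intervention.
#' This is the canonical fixture used throughout the package's examples and
#' tests.
#'
#' @return an [sced_series()] with `T_b = T_t = 6`.
#' @examples
#' p7 <- suppressWarnings(sced_p7())
#' immediacy(p7)
#' @export
sced_p7 <- function() {
  sced_series(
    baseline = c(4.77, 4.78, 2.96, 4.79, 3.99, 4.00),
    treatment = c(3.18, 2.78, 2.99, 2.79, 2.79, 2.20),
    participant_id = "P7",
    outcome_name = "PTCI-SB"
  )
}

norm_phase_label <- function(x) {
  lab <- c(
    "A" = "baseline", "B" = "treatment",
    "1" = "baseline", "2" = "treatment",
    "baseline" = "baseline", "treatment" = "treatment"
  )
  key <- trimws(as.character(x))
  out <- lab[key]
  if (anyNA(out)) {
    bad <- unique(key[is.na(out)])
    stop(sprintf(
      "unknown phase label(s) %s; allowed: A/B, 1/2, baseline/treatment",
      paste(sQuote(bad), collapse = ", ")
    ), call. = FALSE)
  }
  unname(out)
}

parse_cells <- function(x, rows, cols, what = "cell") {
  x <- trimws(x)
  x[x == "NA" | x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    i <- bad[1]
    stop(sprintf(
      "non-numeric %s %s at row %s, column %s",
      what, sQuote(x[i]), rows[i], cols[i]
    ), call. = FALSE)
  }
  out
}

#' Read SCED series from a wide CSV
#'
#' Two layouts are supported. `orientation = "rows"` (default): each
#' participant contributes two consecutive data rows, baseline first then
#' treatment; optional leading columns named `participant` and `phase` label
#' the rows, remaining columns hold the observations in time order.
#' `orientation = "columns"`: each participant contributes two columns named
#' `<id>_baseline` and `<id>_treatment` (suffixes `_A`/`_B` also accepted) and
#' rows are time points.
#'
#' Cells are numeric, the literal token `NA`, or empty; missing cells pad the
#' shorter phase and are stripped. Any other content is a parse error naming
#' the offending row and column.
#'
#' @param path path to a CSV file with a header row.
#' @param orientation `"rows"` or `"columns"` (see above).
#' @param outcome_name outcome label attached to every series.
#' @return list of [sced_series()], one per participant, in file order.
#' @export
read_wide_csv <- function(path, orientation = c("rows", "columns"),
                          outcome_name = "outcome") {
  orientation <- match.arg(orientation)
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (orientation == "columns") {
    return(read_wide_columns(raw, outcome_name))
  }
  cn <- tolower(names(raw))
  id_col <- match("participant", cn)
  ph_col <- match("phase", cn)
  val_cols <- setdiff(seq_along(raw), c(id_col, ph_col))
  if (nrow(raw) == 0L) return(list())
  if (nrow(raw) %% 2L != 0L) {
    stop("wide row layout needs two rows (baseline, treatment) per participant",
         call. = FALSE)
  }
  n_part <- nrow(raw) / 2L
  out <- vector("list", n_part)
  for (k in seq_len(n_part)) {
    i1 <- 2L * k - 1L
    i2 <- 2L * k
    id <- if (!is.na(id_col)) raw[[id_col]][i1] else sprintf("P%d", k)
    if (!is.na(ph_col)) {
      ph <- norm_phase_label(raw[[ph_col]][c(i1, i2)])
      if (!identical(ph, c("baseline", "treatment"))) {
        stop(sprintf(
          "participant '%s': expected phases baseline then treatment, got %s/%s",
          id, ph[1], ph[2]
        ), call. = FALSE)
      }
    }
    vals1 <- parse_cells(unlist(raw[i1, val_cols], use.names = FALSE),
                         rows = rep(i1 + 1L, length(val_cols)),
                         cols = names(raw)[val_cols])
    vals2 <- parse_cells(unlist(raw[i2, val_cols], use.names = FALSE),
                         rows = rep(i2 + 1L, length(val_cols)),
                         cols = names(raw)[val_cols])
    out[[k]] <- sced_series(vals1, vals2, participant_id = id,
                            outcome_name = outcome_name)
  }
  out
}

read_wide_columns <- function(raw, outcome_name) {
  nm <- names(raw)
  suf <- "(_baseline|_treatment|_A|_B)$"
  ids <- unique(sub(suf, "", nm))
  out <- list()
  for (id in ids) {
    bcol <- nm[nm %in% paste0(id, c("_baseline", "_A"))]
    tcol <- nm[nm %in% paste0(id, c("_treatment", "_B"))]
    if (length(bcol) != 1L || length(tcol) != 1L) {
      stop(sprintf(
        "participant '%s': need exactly one baseline and one treatment column (suffixes _baseline/_treatment or _A/_B)",
        id
      ), call. = FALSE)
    }
    b <- parse_cells(raw[[bcol]], rows = seq_len(nrow(raw)) + 1L,
                     cols = rep(bcol, nrow(raw)))
    tr <- parse_cells(raw[[tcol]], rows = seq_len(nrow(raw)) + 1L,
                      cols = rep(tcol, nrow(raw)))
    out[[length(out) + 1L]] <- sced_series(b, tr, participant_id = id,
                                           outcome_name = outcome_name)
  }
  out
}

#' Read SCED series from a tidy long CSV
#'
#' Expects columns `participant,phase,time,value`. Phase labels may be `A`/`B`,
#' `1`/`2` or `baseline`/`treatment`. Within each participant, time must be
#' strictly increasing and free of duplicates; values are numeric or `NA`
#' (missing rows are dropped).
#'
#' @param path path to the CSV file.
#' @param outcome_name outcome label attached to every series.
#' @return list of [sced_series()] in order of first appearance.
#' @export
read_long_csv <- function(path, outcome_name = "outcome") {
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         strip.white = TRUE)
  need <- c("participant", "phase", "time", "value")
  if (!all(need %in% tolower(names(raw)))) {
    stop("long CSV must have columns participant,phase,time,value",
         call. = FALSE)
  }
  names(raw) <- tolower(names(raw))
  if (nrow(raw) == 0L) return(list())
  raw$phase <- norm_phase_label(raw$phase)
  raw$time <- parse_cells(raw$time, rows = seq_len(nrow(raw)) + 1L,
                          cols = rep("time", nrow(raw)), what = "time value")
  raw$value <- parse_cells(raw$value, rows = seq_len(nrow(raw)) + 1L,
                           cols = rep("value", nrow(raw)))
  ids <- unique(raw$participant)
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    d <- raw[raw$participant == ids[k], , drop = FALSE]
    if (anyDuplicated(d$time)) {
      stop(sprintf("participant '%s': duplicate time index", ids[k]),
           call. = FALSE)
    }
    if (is.unsorted(d$time, strictly = TRUE)) {
      stop(sprintf("participant '%s': time must be strictly increasing", ids[k]),
           call. = FALSE)
    }
    out[[k]] <- sced_series(
      d$value[d$phase == "baseline"],
      d$value[d$phase == "treatment"],
      participant_id = ids[k],
      outcome_name = outcome_name
    )
  }
  out
}

#' Write one or more series as a tidy long CSV
#'
#' Values are rendered with `%.17g` so a write/read round trip reproduces the
#' doubles bitwise.
#'
#' @param series an [sced_series()] or a list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(series, path) {
  if (inherits(series, "sced_series")) series <- list(series)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("participant,phase,time,value", con)
  for (s in series) {
    tb <- length(s$baseline)
    vals <- series_values(s)
    ph <- c(rep("A", tb), rep("B", length(s$treatment)))
    writeLines(sprintf("%s,%s,%d,%.17g", s$participant_id, ph,
                       seq_along(vals), vals), con)
  }
  invisible(path)
}

#' Write a posterior summary table as CSV
#'
#' Columns are `parameter,lower95,median,upper95,mean,sd`, rows in reporting
#' order (for BUCP the change point comes first). Values are written with at
#' least four significant digits.
#'
#' @param table a summary table from [summarize_posterior()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  need <- c("parameter", "lower95", "median", "upper95", "mean", "sd")
  if (!all(need %in% names(table))) {
    stop("summary table must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(need, collapse = ","), con)
  if (nrow(table)) {
    # parameter names contain commas (beta[1,1]), so that field is quoted
    writeLines(sprintf(
      "\"%s\",%s,%s,%s,%s,%s",
      table$parameter,
      as.character(signif(table$lower95, 6)),
      as.character(signif(table$median, 6)),
      as.character(signif(table$upper95, 6)),
      as.character(signif(table$mean, 6)),
      as.character(signif(table$sd, 6))
    ), con)
  }
  invisible(path)
}

#' Dump posterior draws as CSV
#'
#' One row per draw and parameter: `chain,iteration,parameter,value`.
#'
#' @param samples a [fit_sced()] result.
#' @param path output path.
#' @param parameters optional subset of parameter names.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(samples, path, parameters = NULL) {
  stopifnot(inherits(samples, "sced_posterior"))
  pars <- parameters %||% colnames(samples$draws[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("chain,iteration,parameter,value", con)
  for (ch in seq_along(samples$draws)) {
    m <- samples$draws[[ch]]
    for (p in pars) {
      writeLines(sprintf("%d,%d,%s,%.17g", ch, seq_len(nrow(m)), p, m[, p]),
                 con)
    }
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
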