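test_that("wide CSV fixture parses to the worked-example series", {
  path <- system.file("extdata", "p7_selfblame_wide.csv", package = "scedbayes")
  s <- suppressWarnings(read_wide_csv(path))
  expect_length(s, 1)
  expect_equal(s[[1]]$participant_id, "P7")
  expect_equal(s[[1]]$baseline, c(4.77, 4.78, 2.96, 4.79, 3.99, 4.00))
  expect_equal(s[[1]]$treatment, c(3.18, 2.78, 2.99, 2.79, 2.79, 2.20))
})

test_that("NA cells pad the shorter phase and are stripped", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t1,t2,t3,t4", "1,2,3,NA", "4,5,6,7"), f)
  s <- suppressWarnings(read_wide_csv(f))
  expect_equal(length(s[[1]]$baseline), 3)
  expect_equal(length(s[[1]]$treatment), 4)
  expect_equal(s[[1]]$treatment, c(4, 5, 6, 7))
})

test_that("a phase with fewer than 3 non-NA values is rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t1,t2,t3", "1,2,3", "4,5,NA"), f)
  expect_error(read_wide_csv(f), "at least 3")
})

test_that("non-numeric cells raise a parse error naming row and column", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t1,t2,t3", "1,oops,3", "4,5,6"), f)
  expect_error(read_wide_csv(f), "oops.*row 2.*column t2")
})

test_that("column-oriented wide layout parses", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("P9_baseline,P9_treatment", "1,4", "2,5", "3,6", "NA,7"), f)
  s <- suppressWarnings(read_wide_csv(f, orientation = "columns"))
  expect_equal(s[[1]]$participant_id, "P9")
  expect_equal(s[[1]]$baseline, c(1, 2, 3))
  expect_equal(s[[1]]$treatment, c(4, 5, 6, 7))
})

test_that("long and wide encodings of the same data agree", {
  wide <- suppressWarnings(read_wide_csv(
    system.file("extdata", "p7_selfblame_wide.csv", package = "scedbayes")
  ))
  long <- suppressWarnings(read_long_csv(
    system.file("extdata", "p7_selfblame_long.csv", package = "scedbayes")
  ))
  expect_equal(wide[[1]]$baseline, long[[1]]$baseline)
  expect_equal(wide[[1]]$treatment, long[[1]]$treatment)
  expect_equal(wide[[1]]$participant_id, long[[1]]$participant_id)
})

test_that("long CSV validation catches bad input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("participant,phase,time,value", f)
  expect_length(read_long_csv(f), 0)

  writeLines(c("participant,phase,time,value", "P1,C,1,2"), f)
  expect_error(read_long_csv(f), "A/B, 1/2, baseline/treatment")

  writeLines(c("participant,phase,time,value",
               "P1,A,1,1", "P1,A,1,2", "P1,A,3,3",
               "P1,B,4,1", "P1,B,5,2", "P1,B,6,3"), f)
  expect_error(read_long_csv(f), "duplicate time")

  writeLines(c("participant,phase,time,value",
               "P1,A,1,1", "P1,A,3,2", "P1,A,2,3",
               "P1,B,4,1", "P1,B,5,2", "P1,B,6,3"), f)
  expect_error(read_long_csv(f), "strictly increasing")
})

test_that("long-CSV round trip is bitwise exact", {
  set.seed(42)
  for (i in 1:5) {
    s <- rand_series()
    f <- withr::local_tempfile(fileext = ".csv")
    write_long_csv(s, f)
    back <- suppressWarnings(read_long_csv(f))[[1]]
    expect_identical(back$baseline, s$baseline)
    expect_identical(back$treatment, s$treatment)
  }
})

test_that("summary CSV has the reporting layout", {
  fit <- fit_sced(p7_quiet(), "bits", config = quick_config(n_retained = 500))
  f <- withr::local_tempfile(fileext = ".csv")
  write_summary_csv(summarize_posterior(fit), f)
  got <- read.csv(f)
  expect_equal(names(got), c("parameter", "lower95", "median", "upper95",
                             "mean", "sd"))
  expect_equal(got$parameter, c("beta[1,1]", "beta[2,1]", "sigma", "rho", "es"))

  fitb <- fit_sced(p7_quiet(), "bucp", config = quick_config(n_retained = 500))
  write_summary_csv(summarize_posterior(fitb), f)
  gotb <- read.csv(f)
  expect_equal(nrow(gotb), 6)
  expect_equal(gotb$parameter[1], "CP")

  empty <- data.frame(parameter = character(), lower95 = numeric(),
                      median = numeric(), upper95 = numeric(),
                      mean = numeric(), sd = numeric())
  write_summary_csv(empty, f)
  expect_equal(readLines(f), "parameter,lower95,median,upper95,mean,sd")
})

test_that("draw dump CSV round-trips a parameter", {
  fit <- fit_sced(p7_quiet(), "bits", config = quick_config(n_retained = 200))
  f <- withr::local_tempfile(fileext = ".csv")
  write_draws_csv(fit, f, parameters = "es")
  d <- read.csv(f)
  expect_equal(nrow(d), 4 * 200)
  expect_identical(d$value[d$chain == 2], unname(fit$draws[[2]][, "es"]))
})

test_that("prior specifications round-trip through JSON", {
  pr <- prior_spec(mu_prec = 0.1, sigma_high = 3,
                   cp_weights = c(1, 1, 2, 1, 1, 1))
  f <- withr::local_tempfile(fileext = ".json")
  write_prior_spec(pr, f)
  back <- read_prior_spec(f)
  expect_equal(back, pr)
  # unknown fields are rejected rather than silently dropped
  writeLines('{"beta_prec": 1, "bogus": 2}', f)
  expect_error(read_prior_spec(f), "unknown prior fields")
})
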