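test_that("prior initialization is seeded and respects the support", {
  pr <- prior_spec()
  a <- init_from_prior(pr, "bucp", n_time = 12, seed = 99)
  b <- init_from_prior(pr, "bucp", n_time = 12, seed = 99)
  expect_identical(a, b)

  set.seed(5)
  draws <- replicate(1000, {
    st <- init_from_prior(pr, "bucp", n_time = 12)
    expect_gt(st$sigma_eps, pr$sigma_low)
    expect_lt(st$sigma_eps, pr$sigma_high)
    expect_true(st$rho > -1 && st$rho < 1)
    expect_true(st$cp %in% 4:9)
    st$mu1
  })
  # hyperprior is N(5, var 20): Monte-Carlo check of the mean
  expect_lt(abs(mean(draws) - 5), 3 * sqrt(20 / 1000))
})

test_that("intercept full conditionals match closed forms", {
  set.seed(3)
  y <- rnorm(9, 4, 1)
  # rho = 0: textbook normal-normal posterior
  fc <- scedbayes:::beta_fc_bits_cpp(y, 0, 0.8, 1.3, 5)
  prec <- 1.3 + length(y) / 0.8^2
  expect_equal(fc[1], (1.3 * 5 + sum(y) / 0.8^2) / prec, tolerance = 1e-10)
  expect_equal(fc[2], 1 / sqrt(prec), tolerance = 1e-10)

  # random rho: generalized least squares with the AR covariance oracle
  for (i in 1:10) {
    rho <- runif(1, -0.9, 0.9)
    sigma <- runif(1, 0.4, 1.5)
    S <- ar1_cov(length(y), sigma, rho)
    Sinv1 <- solve(S, rep(1, length(y)))
    prec <- 1 + sum(Sinv1)
    mean_gls <- (1 * 5 + sum(Sinv1 * y)) / prec
    fc <- scedbayes:::beta_fc_bits_cpp(y, rho, sigma, 1, 5)
    expect_equal(fc[1], mean_gls, tolerance = 1e-8)
    expect_equal(fc[2], 1 / sqrt(prec), tolerance = 1e-8)
  }
})

test_that("joint BUCP intercept full conditional matches GLS", {
  set.seed(4)
  y <- rnorm(12, 4, 1)
  for (cp in c(4, 6, 9)) {
    rho <- runif(1, -0.8, 0.8)
    sigma <- runif(1, 0.5, 1.2)
    X <- cbind(as.numeric(1:12 <= cp), as.numeric(1:12 > cp))
    S <- ar1_cov(12, sigma, rho)
    P <- diag(2) + t(X) %*% solve(S, X)
    m <- solve(P, c(5, 3) + t(X) %*% solve(S, y))
    fc <- scedbayes:::beta_fc_bucp_cpp(y, cp, rho, sigma, 1, 5, 3)
    expect_equal(as.numeric(fc$mean), as.numeric(m), tolerance = 1e-8)
    expect_equal(fc$cov, solve(P), tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("near-degenerate priors collapse the intercepts to phase means", {
  # sigma and rho pinned; long series so the likelihood dominates
  spec <- simulation_spec(beta1 = 5, beta2 = 2, sigma_eps = 1, rho = 0,
                          T_b = 300, T_t = 300, seed = 8)
  s <- simulate_sced(spec)
  pr <- prior_spec(sigma_low = 0.999, sigma_high = 1.001,
                   rho_low = -0.001, rho_high = 0.001, beta_prec = 100)
  fit <- fit_sced(s, "bits", prior = pr,
                  config = quick_config(n_retained = 2000))
  sm <- summarize_posterior(fit, parameters = c("beta[1,1]", "beta[2,1]"))
  # closed-form conjugate posterior mean at sigma = 1, rho = 0, with the
  # marginal prior beta ~ N(5, 1/100 + 20)
  v0 <- 1 / 100 + 20
  shrink <- function(y) (mean(y) * length(y) + 5 / v0) / (length(y) + 1 / v0)
  expect_equal(sm$mean[1], shrink(s$baseline), tolerance = 0.02)
  expect_equal(sm$mean[2], shrink(s$treatment), tolerance = 0.02)
})

test_that("an enormous level shift is found with near-certainty", {
  spec <- simulation_spec(beta1 = 10, beta2 = 0, sigma_eps = 1, rho = 0.2,
                          T_b = 8, T_t = 7, seed = 21)
  s <- simulate_sced(spec)
  fit <- fit_sced(s, "bucp", config = quick_config(n_retained = 2000))
  cpr <- cp_mode_and_table(fit)
  expect_equal(cpr$mode, 8)
  expect_gt(cpr$table[["8"]], 0.99)
})

test_that("cp_full_conditional enumerates the normalized full conditional", {
  flat <- suppressWarnings(sced_series(rep(3, 6), rep(3, 6)))
  st <- model_state(3, 3, sigma_eps = 1, rho = 0.2)
  p <- cp_full_conditional(flat, st)
  expect_equal(sum(p), 1)
  expect_equal(unname(p), rep(1 / 6, 6))

  p7 <- p7_quiet()
  st <- model_state(4.06, 2.84, sigma_eps = 0.72, rho = 0.12)
  p <- cp_full_conditional(p7, st)
  expect_equal(names(which.max(p)), "6")

  spike <- prior_spec(cp_weights = c(0, 0, 0, 1, 0, 0))
  p <- cp_full_conditional(p7, st, spike)
  expect_equal(unname(p[4]), 1)

  short <- suppressWarnings(sced_series(1:3, 4:6))
  expect_error(cp_full_conditional(short, st), "first three")
})

test_that("retained draws satisfy their invariants", {
  p7 <- p7_quiet()
  fit <- fit_sced(p7, "bucp", config = quick_config(n_retained = 1500))
  for (m in fit$draws) {
    expect_identical(
      m[, "es"],
      (m[, "beta[1,1]"] - m[, "beta[2,1]"]) / m[, "sigma"]
    )
    expect_true(all(m[, "sigma"] > 0.1 & m[, "sigma"] < 5))
    expect_true(all(m[, "rho"] > -1 & m[, "rho"] < 1))
    expect_true(all(m[, "CP"] == round(m[, "CP"])))
    expect_true(all(m[, "CP"] %in% 4:9))
  }
})

test_that("fits are reproducible and config is validated", {
  p7 <- p7_quiet()
  f1 <- fit_sced(p7, "bits", config = quick_config(seed = 77, n_retained = 300))
  f2 <- fit_sced(p7, "bits", config = quick_config(seed = 77, n_retained = 300))
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_sced(p7, "bits", config = quick_config(seed = 78, n_retained = 300))
  expect_false(identical(f1$draws, f3$draws))

  expect_error(sampler_config(n_chains = 1), "n_chains")
  short <- suppressWarnings(sced_series(1:3, 4:6))
  expect_error(fit_sced(short, "bucp"), "T >= 7")
})

test_that("interval coverage is near nominal on well-specified data", {
  # scaled-down recovery smoke test; the full study runs in the acceptance suite
  rep <- recovery_study(
    simulation_spec(beta1 = 5, beta2 = 2, sigma_eps = 1, rho = 0.2, seed = 1),
    n_reps = 6, model = "bits",
    config = quick_config(n_retained = 1500)
  )
  cov_beta <- rep$params$coverage[rep$params$parameter %in%
                                    c("beta[1,1]", "beta[2,1]")]
  expect_true(all(cov_beta >= 0.5)) # loose band at n_reps = 6
  expect_lt(abs(rep$params$bias[rep$params$parameter == "es"]), 1)
})
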