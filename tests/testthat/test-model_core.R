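test_that("phase means are intercept-only and the change point switches them", {
  st <- model_state(4.24, 2.82, cp = 6)
  expect_equal(predicted_mean_bits(st, 1), 4.24)
  expect_equal(predicted_mean_bits(st, 2), 2.82)
  expect_error(predicted_mean_bits(st, 3), "phase")

  expect_equal(predicted_mean_bucp(st, 6, 12), 4.24)
  expect_equal(predicted_mean_bucp(st, 7, 12), 2.82)
  st4 <- model_state(1, 2, cp = 4)
  expect_equal(predicted_mean_bucp(st4, 1, 12), 1)
  st9 <- model_state(1, 2, cp = 9)
  expect_equal(predicted_mean_bucp(st9, 12, 12), 2)
  expect_error(predicted_mean_bucp(st, 13, 12), "out of range")
})

test_that("bits_loglik reduces to the iid likelihood at rho = 0", {
  p7 <- p7_quiet()
  st <- model_state(4.2, 2.8, sigma_eps = 0.7, rho = 0)
  iid <- sum(dnorm(p7$baseline, 4.2, 0.7, log = TRUE)) +
    sum(dnorm(p7$treatment, 2.8, 0.7, log = TRUE))
  expect_equal(bits_loglik(p7, st), iid)
})

test_that("exact-fit residuals cancel the AR term", {
  s <- suppressWarnings(sced_series(c(2, 2, 2), c(5, 5, 5)))
  st <- model_state(2, 5, sigma_eps = 1, rho = 0.5)
  expect_equal(bits_loglik(s, st), 6 * dnorm(0, 0, 1, log = TRUE))
})

test_that("bits_loglik agrees with the joint multivariate-normal oracle", {
  set.seed(7)
  for (i in 1:25) {
    s <- rand_series()
    st <- rand_state()
    expect_equal(bits_loglik(s, st), bits_loglik_oracle(s, st),
                 tolerance = 1e-10)
  }
  # the compiled likelihood used inside the sampler matches the R one
  p7 <- p7_quiet()
  st <- model_state(4.22, 2.81, sigma_eps = 0.62, rho = -0.21)
  expect_equal(
    scedbayes:::bits_loglik_cpp(p7$baseline, p7$treatment,
                                st$beta1, st$beta2, st$sigma_eps, st$rho),
    bits_loglik(p7, st), tolerance = 1e-12
  )
  expect_equal(bits_loglik(p7, st), bits_loglik_oracle(p7, st),
               tolerance = 1e-10)
})

test_that("bucp_loglik is one unbroken chain", {
  p7 <- p7_quiet()
  # rho = 0: same factorization as BITS when CP sits at the true boundary
  st0 <- model_state(4.1, 2.9, sigma_eps = 0.7, rho = 0, cp = 6)
  expect_equal(bucp_loglik(p7, st0), bits_loglik(p7, st0))

  # rho != 0: differs by exactly one term - the first treatment observation
  # is conditioned on the last baseline one instead of unconditioned
  st <- model_state(4.1, 2.9, sigma_eps = 0.7, rho = 0.4, cp = 6)
  y7 <- p7$treatment[1]
  y6 <- p7$baseline[6]
  boundary <- dnorm(y7, st$beta2 + st$rho * (y6 - st$beta1), st$sigma_eps,
                    log = TRUE) -
    dnorm(y7, st$beta2, st$sigma_eps, log = TRUE)
  expect_equal(bucp_loglik(p7, st) - bits_loglik(p7, st), boundary)

  # and against the MVN oracle over the whole chain
  set.seed(11)
  for (i in 1:25) {
    s <- rand_series(n_b = 5, n_t = 6)
    st <- rand_state(cp = sample(4:8, 1))
    expect_equal(bucp_loglik(s, st), bucp_loglik_oracle(s, st),
                 tolerance = 1e-10)
    expect_equal(
      scedbayes:::bucp_loglik_cpp(series_values(s), st$cp, st$beta1, st$beta2,
                                  st$sigma_eps, st$rho),
      bucp_loglik(s, st), tolerance = 1e-12
    )
  }
})

test_that("the true boundary maximizes the P7 likelihood over change points", {
  p7 <- p7_quiet()
  st <- model_state(4.06, 2.84, sigma_eps = 0.72, rho = 0.12)
  ll <- vapply(4:9, function(cp) {
    st$cp <- cp
    bucp_loglik(p7, st)
  }, numeric(1))
  expect_gt(ll[3], ll[1]) # CP=6 beats CP=4
  expect_gt(ll[3], ll[6]) # CP=6 beats CP=9
  expect_equal((4:9)[which.max(ll)], 6)
})

test_that("log_prior matches its factor structure and support", {
  pr <- prior_spec()
  st <- model_state(4, 3, mu1 = 4.5, mu2 = 3.5, sigma_eps = 0.8, rho = 0.1)
  expect_equal(
    log_prior(st, pr, "bits"),
    dnorm(4, 4.5, 1, log = TRUE) + dnorm(3, 3.5, 1, log = TRUE) +
      dnorm(4.5, 5, sqrt(20), log = TRUE) + dnorm(3.5, 5, sqrt(20), log = TRUE) +
      log(1 / 4.9) + log(1 / 2)
  )
  st$sigma_eps <- 6
  expect_identical(log_prior(st, pr, "bits"), -Inf)
  st$sigma_eps <- 0.8
  st$rho <- 1.5
  expect_identical(log_prior(st, pr, "bits"), -Inf)
  st$rho <- 0.1

  # uniform change-point prior over {4..9} contributes log(1/6)
  st$cp <- 5L
  expect_equal(
    log_prior(st, pr, "bucp", n_time = 12) - log_prior(st, pr, "bits"),
    log(1 / 6)
  )
  st$cp <- 3L
  expect_identical(log_prior(st, pr, "bucp", n_time = 12), -Inf)
})

test_that("uniform and categorical prior factors are normalized", {
  pr <- prior_spec()
  st <- model_state(4, 3, sigma_eps = 1, rho = 0, cp = 5L)
  base <- log_prior(st, pr, "bits")
  f_sigma <- Vectorize(function(s) {
    st$sigma_eps <- s
    exp(log_prior(st, pr, "bits") - base)
  })
  expect_equal(integrate(f_sigma, 0.1, 5)$value, 4.9, tolerance = 1e-6)
  f_rho <- Vectorize(function(r) {
    st$rho <- r
    exp(log_prior(st, pr, "bits") - base)
  })
  expect_equal(integrate(f_rho, -1, 1)$value, 2, tolerance = 1e-6)
  # exp(lp_bucp(cp) - lp_bits) recovers w_cp; the weights must sum to 1
  weights <- vapply(4:9, function(cp) {
    st$cp <- cp
    exp(log_prior(st, pr, "bucp", n_time = 12) - base)
  }, numeric(1))
  expect_equal(sum(weights), 1)
})

test_that("white_noise_sd implements the AR(1) variance identity", {
  expect_equal(white_noise_sd(1, 0), 1)
  expect_equal(white_noise_sd(1, 0.6), 0.8)
  expect_equal(white_noise_sd(0.66, -0.17), 0.66 * sqrt(1 - 0.17^2))
  expect_error(white_noise_sd(1, 1), "rho")
})

test_that("effect_size is the standardized intercept difference", {
  expect_equal(effect_size(model_state(3, 3)), 0)
  expect_equal(effect_size(model_state(3, 1, sigma_eps = 1)), 2)
  expect_equal(effect_size(model_state(5, 2, sigma_eps = 2)), 1.5)
})
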