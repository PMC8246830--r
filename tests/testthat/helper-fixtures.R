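# Shared fixtures and independent oracles. The oracles deliberately take the
# joint multivariate-normal route (explicit covariance from the AR recursion)
# so they share no code path with the conditional-factorization likelihoods
# they check.

p7_quiet <- function() suppressWarnings(sced_p7())

quick_config <- function(seed = 1, n_retained = 3000, n_burnin = 500,
                         n_adapt = 500, n_chains = 4) {
  sampler_config(n_chains = n_chains, n_retained = n_retained,
                 n_burnin = n_burnin, n_adapt = n_adapt, seed = seed)
}

# Covariance of AR(1) residuals started cold: Var(e_1) = sigma^2,
# Var(e_t) = rho^2 Var(e_{t-1}) + sigma^2, Cov(e_t, e_{t+k}) = rho^k Var(e_t).
ar1_cov <- function(n, sigma, rho) {
  v <- numeric(n)
  v[1] <- sigma^2
  if (n > 1) for (t in 2:n) v[t] <- rho^2 * v[t - 1] + sigma^2
  S <- matrix(0, n, n)
  for (t in 1:n) {
    for (u in t:n) {
      S[t, u] <- S[u, t] <- rho^(u - t) * v[t]
    }
  }
  S
}

mvn_loglik <- function(y, mu, S) {
  ch <- chol(S)
  u <- backsolve(ch, y - mu, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(u^2)
}

# brute-force BITS log-likelihood: independent MVN per phase
bits_loglik_oracle <- function(series, state) {
  nb <- length(series$baseline)
  nt <- length(series$treatment)
  mvn_loglik(series$baseline, rep(state$beta1, nb),
             ar1_cov(nb, state$sigma_eps, state$rho)) +
    mvn_loglik(series$treatment, rep(state$beta2, nt),
               ar1_cov(nt, state$sigma_eps, state$rho))
}

# brute-force BUCP log-likelihood: one MVN over the whole chain,
# step-function mean
bucp_loglik_oracle <- function(series, state) {
  y <- series_values(series)
  n <- length(y)
  mu <- ifelse(seq_len(n) <= state$cp, state$beta1, state$beta2)
  mvn_loglik(y, mu, ar1_cov(n, state$sigma_eps, state$rho))
}

rand_series <- function(n_b = NULL, n_t = NULL) {
  n_b <- n_b %||% sample(3:8, 1)
  n_t <- n_t %||% sample(3:8, 1)
  suppressWarnings(sced_series(rnorm(n_b, 5, 1), rnorm(n_t, 3, 1)))
}

rand_state <- function(cp = NULL) {
  model_state(
    beta1 = rnorm(1, 4, 1), beta2 = rnorm(1, 3, 1),
    sigma_eps = runif(1, 0.3, 2), rho = runif(1, -0.9, 0.9), cp = cp
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built posterior container for summary-level tests
fake_posterior <- function(chains, model = "bits", series = p7_quiet()) {
  structure(
    list(draws = chains, model = model, series = series,
         prior = prior_spec(), config = quick_config()),
    class = "sced_posterior"
  )
}
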