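#' MCMC sampler configuration
#'
#' Defaults follow the reference analysis workflow: four parallel chains, a
#' warm-up of 1,000 adaptation plus 5,000 burn-in sweeps whose draws are
#' discarded, and 30,000 retained draws per chain. Proposal scales for the
#' random-walk updates of `sigma` and `rho` are tuned toward an acceptance
#' rate of 0.44 (the optimum for scalar updates) during warm-up only, then
#' frozen so the retained chain is Markovian.
#'
#' @param n_chains number of chains (>= 2; the convergence diagnostics need at
#'   least two).
#' @param n_retained retained draws per chain after warm-up.
#' @param n_burnin burn-in sweeps discarded after adaptation.
#' @param n_adapt adaptation sweeps (also discarded).
#' @param seed master seed; per-chain streams are derived from it.
#' @param target_accept Metropolis acceptance target in (0, 1).
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 4, n_retained = 30000, n_burnin = 5000,
                           n_adapt = 1000, seed = 1, target_accept = 0.44) {
  stopifnot(
    n_chains >= 2, n_retained > 0, n_burnin > 0, n_adapt > 0,
    target_accept > 0, target_accept < 1
  )
  structure(
    list(n_chains = as.integer(n_chains), n_retained = as.integer(n_retained),
         n_burnin = as.integer(n_burnin), n_adapt = as.integer(n_adapt),
         seed = as.integer(seed), target_accept = target_accept),
    class = "sampler_config"
  )
}

#' Draw a starting state from the prior
#'
#' Every parameter is drawn independently from its prior: the hypermeans from
#' the hyperprior, the intercepts given those hypermeans, `sigma` and `rho`
#' from their uniform priors, and (for BUCP) the change point from its
#' categorical prior. Dispersed prior draws give the between-chain variance
#' that the convergence diagnostics rely on.
#'
#' @param prior a [prior_spec()].
#' @param model `"bits"` or `"bucp"`.
#' @param n_time series length, required for `"bucp"`.
#' @param seed optional seed for reproducible draws.
#' @return a [model_state()].
#' @export
init_from_prior <- function(prior, model = c("bits", "bucp"), n_time = NULL,
                            seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(prior, "prior_spec"))
  if (!is.null(seed)) set.seed(seed)
  mu1 <- stats::rnorm(1, prior$mu_mean, 1 / sqrt(prior$mu_prec))
  mu2 <- stats::rnorm(1, prior$mu_mean, 1 / sqrt(prior$mu_prec))
  b1 <- stats::rnorm(1, mu1, 1 / sqrt(prior$beta_prec))
  b2 <- stats::rnorm(1, mu2, 1 / sqrt(prior$beta_prec))
  sigma <- stats::runif(1, prior$sigma_low, prior$sigma_high)
  rho <- stats::runif(1, prior$rho_low, prior$rho_high)
  cp <- NULL
  if (model == "bucp") {
    if (is.null(n_time)) stop("n_time is required for model = 'bucp'", call. = FALSE)
    sup <- cp_support(n_time)
    w <- cp_prior_weights(prior, n_time)
    cp <- sup[sample.int(length(sup), 1L, prob = w)]
  }
  model_state(b1, b2, mu1, mu2, sigma_eps = sigma, rho = rho, cp = cp)
}

bits_param_names <- c("beta[1,1]", "beta[2,1]", "mu[1]", "mu[2]",
                      "sigma", "rho", "es")
bucp_param_names <- c("beta[1,1]", "beta[2,1]", "mu[1]", "mu[2]",
                      "sigma", "rho", "CP", "es")

#' Fit a BITS or BUCP model by Metropolis-within-Gibbs
#'
#' One sweep updates, in order: the hypermeans `mu[1]`, `mu[2]` by their exact
#' conjugate normal full conditionals; the intercepts by their exact conjugate
#' normal full conditionals (jointly bivariate for BUCP, where the
#' quasi-differenced design couples the two phases); `sigma` and `rho` by
#' adaptive random-walk Metropolis on the constrained scale; and, for BUCP,
#' the change point by exact categorical Gibbs over its full support. The
#' standardized effect size `es = (beta[1,1] - beta[2,1]) / sigma` is appended
#' to every retained draw.
#'
#' Chains start from independent prior draws. Per-chain seeds are derived
#' deterministically from `config$seed`.
#'
#' @param series an [sced_series()].
#' @param model `"bits"` or `"bucp"`.
#' @param prior a [prior_spec()].
#' @param config a [sampler_config()].
#' @return an object of class `sced_posterior`: a list with `draws` (one
#'   `n_retained` x parameters matrix per chain), `model`, `series`, `prior`,
#'   `config`.
#' @examples
#' \donttest{
#' p7 <- suppressWarnings(sced_p7())
#' fit <- fit_sced(p7, "bits", config = sampler_config(n_retained = 2000))
#' summarize_posterior(fit)
#' }
#' @export
fit_sced <- function(series, model = c("bits", "bucp"), prior = prior_spec(),
                     config = sampler_config()) {
  model <- match.arg(model)
  stopifnot(inherits(series, "sced_series"), inherits(prior, "prior_spec"),
            inherits(config, "sampler_config"))
  n <- phase_lengths(series)
  n_warmup <- config$n_adapt + config$n_burnin
  prior_list <- unclass(prior)

  set.seed(config$seed)
  chain_seeds <- sample.int(2147483646L, config$n_chains)

  draws <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(chain_seeds[ch])
    if (model == "bits") {
      st <- init_from_prior(prior, "bits")
      m <- run_bits_chain_cpp(
        series$baseline, series$treatment, prior_list,
        c(st$beta1, st$beta2, st$mu1, st$mu2, st$sigma_eps, st$rho),
        n_warmup, config$n_retained, 50L, config$target_accept
      )
      colnames(m) <- bits_param_names
    } else {
      sup <- cp_support(n$T)
      w <- cp_prior_weights(prior, n$T)
      st <- init_from_prior(prior, "bucp", n_time = n$T)
      m <- run_bucp_chain_cpp(
        series_values(series), prior_list,
        c(st$beta1, st$beta2, st$mu1, st$mu2, st$sigma_eps, st$rho, st$cp),
        min(sup), max(sup), log(w),
        n_warmup, config$n_retained, 50L, config$target_accept
      )
      colnames(m) <- bucp_param_names
    }
    draws[[ch]] <- m
  }
  structure(
    list(draws = draws, model = model, series = series, prior = prior,
         config = config),
    class = "sced_posterior"
  )
}

#' @export
print.sced_posterior <- function(x, ...) {
  cat(sprintf(
    "<sced_posterior> %s fit to participant %s: %d chains x %d draws\n",
    toupper(x$model), x$series$participant_id, length(x$draws),
    nrow(x$draws[[1]])
  ))
  print(summarize_posterior(x))
  invisible(x)
}

#' Pooled posterior draws of one parameter
#'
#' Concatenates the retained draws of all chains (combine-then-summarize).
#'
#' @param samples a [fit_sced()] result.
#' @param parameter parameter name, e.g. `"es"` or `"beta[1,1]"`.
#' @return numeric vector of length `n_chains * n_retained`.
#' @export
pooled_draws <- function(samples, parameter) {
  stopifnot(inherits(samples, "sced_posterior"))
  if (!parameter %in% colnames(samples$draws[[1]])) {
    stop(sprintf("unknown parameter '%s'; available: %s", parameter,
                 paste(colnames(samples$draws[[1]]), collapse = ", ")),
         call. = FALSE)
  }
  unlist(lapply(samples$draws, function(m) m[, parameter]), use.names = FALSE)
}

#' Full conditional distribution of the change point
#'
#' Enumerates the admissible change points `{4..T-3}` and returns the
#' normalized probabilities proportional to the BUCP likelihood at each change
#' point times the prior weight, holding all other parameters at `state`.
#'
#' @param series an [sced_series()] with total length >= 7.
#' @param state a [model_state()] (its `cp`, if any, is ignored).
#' @param prior a [prior_spec()].
#' @return named probability vector over the support (names are the change
#'   points); sums to 1.
#' @export
cp_full_conditional <- function(series, state, prior = prior_spec()) {
  stopifnot(inherits(series, "sced_series"), inherits(state, "model_state"))
  n <- phase_lengths(series)$T
  sup <- cp_support(n)
  w <- cp_prior_weights(prior, n)
  lp <- vapply(seq_along(sup), function(j) {
    st <- state
    st$cp <- sup[j]
    bucp_loglik(series, st) + log(w[j])
  }, numeric(1))
  p <- exp(lp - max(lp[is.finite(lp)]))
  p[!is.finite(p)] <- 0
  p <- p / sum(p)
  names(p) <- sup
  p
}
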