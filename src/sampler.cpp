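#include <Rcpp.h>
using namespace Rcpp;

// AR(1)-error intercept model for one phase; conditioning restarts at the
// phase start (first observation unconditional with SD sigma).
static double phase_ll(const NumericVector& y, double b, double sigma,
                       double rho) {
  const int n = y.size();
  double ll = R::dnorm(y[0], b, sigma, 1);
  for (int t = 1; t < n; ++t)
    ll += R::dnorm(y[t], b + rho * (y[t - 1] - b), sigma, 1);
  return ll;
}

// [[Rcpp::export]]
double bits_loglik_cpp(NumericVector yb, NumericVector yt, double b1,
                       double b2, double sigma, double rho) {
  return phase_ll(yb, b1, sigma, rho) + phase_ll(yt, b2, sigma, rho);
}

// Single unbroken AR(1) chain with a step-function mean: mean is b1 for
// t <= cp (1-based), b2 after. No restart at the change point.
// [[Rcpp::export]]
double bucp_loglik_cpp(NumericVector y, int cp, double b1, double b2,
                       double sigma, double rho) {
  const int n = y.size();
  double mprev = (1 <= cp) ? b1 : b2;
  double ll = R::dnorm(y[0], mprev, sigma, 1);
  for (int t = 1; t < n; ++t) {
    const double m = ((t + 1) <= cp) ? b1 : b2;
    ll += R::dnorm(y[t], m + rho * (y[t - 1] - mprev), sigma, 1);
    mprev = m;
  }
  return ll;
}

// Normal full conditional of one phase intercept given rho, sigma.
// Quasi-differencing y_t - rho*y_{t-1} makes the model linear-Gaussian with
// coefficient 1 on the first observation and (1 - rho) on the rest.
// [[Rcpp::export]]
NumericVector beta_fc_bits_cpp(NumericVector y, double rho, double sigma,
                               double beta_prec, double mu) {
  const int n = y.size();
  const double s2 = sigma * sigma;
  double c2 = 1.0, cz = y[0];
  for (int t = 1; t < n; ++t) {
    c2 += (1.0 - rho) * (1.0 - rho);
    cz += (1.0 - rho) * (y[t] - rho * y[t - 1]);
  }
  const double prec = beta_prec + c2 / s2;
  const double mean = (beta_prec * mu + cz / s2) / prec;
  return NumericVector::create(mean, 1.0 / std::sqrt(prec));
}

// Bivariate normal full conditional of (b1, b2) for the change-point model:
// design row at t is x_t - rho * x_{t-1} (x_t one-hot in the phase),
// response y_t - rho * y_{t-1}; first row is x_1, y_1.
// Returns mean (2), covariance (2x2).
// [[Rcpp::export]]
List beta_fc_bucp_cpp(NumericVector y, int cp, double rho, double sigma,
                      double beta_prec, double mu1, double mu2) {
  const int n = y.size();
  const double s2 = sigma * sigma;
  double a11 = 0, a12 = 0, a22 = 0, z1 = 0, z2 = 0;
  double xprev1 = 0, xprev2 = 0;
  for (int t = 0; t < n; ++t) {
    const double x1 = ((t + 1) <= cp) ? 1.0 : 0.0;
    const double x2 = 1.0 - x1;
    double a1, a2, z;
    if (t == 0) {
      a1 = x1; a2 = x2; z = y[0];
    } else {
      a1 = x1 - rho * xprev1;
      a2 = x2 - rho * xprev2;
      z = y[t] - rho * y[t - 1];
    }
    a11 += a1 * a1; a12 += a1 * a2; a22 += a2 * a2;
    z1 += a1 * z; z2 += a2 * z;
    xprev1 = x1; xprev2 = x2;
  }
  const double p11 = beta_prec + a11 / s2;
  const double p12 = a12 / s2;
  const double p22 = beta_prec + a22 / s2;
  const double det = p11 * p22 - p12 * p12;
  NumericMatrix cov(2, 2);
  cov(0, 0) = p22 / det; cov(1, 1) = p11 / det;
  cov(0, 1) = cov(1, 0) = -p12 / det;
  const double r1 = beta_prec * mu1 + z1 / s2;
  const double r2 = beta_prec * mu2 + z2 / s2;
  NumericVector mean = NumericVector::create(
    cov(0, 0) * r1 + cov(0, 1) * r2,
    cov(1, 0) * r1 + cov(1, 1) * r2);
  return List::create(_["mean"] = mean, _["cov"] = cov);
}

struct AdaptScale {
  double ls;        // log proposal SD
  int acc, tries;   // counters within the current batch
  int batch;
  double target;
  AdaptScale(double init_ls, double target_)
    : ls(init_ls), acc(0), tries(0), batch(0), target(target_) {}
  void tally(bool accepted) { ++tries; if (accepted) ++acc; }
  // call every `interval` iterations during warmup only
  void adapt() {
    ++batch;
    if (tries == 0) return;
    const double rate = double(acc) / double(tries);
    const double step = std::min(0.5, 2.0 / std::sqrt(double(batch)));
    ls += step * (rate - target);
    acc = 0; tries = 0;
  }
};

static void check_finite(double ll) {
  if (!R_finite(ll))
    stop("non-finite log-likelihood encountered during sampling");
}

// One adaptive random-walk Metropolis step on a uniform-(lo,hi) parameter.
// The uniform prior is flat inside the support, so the acceptance ratio is a
// pure likelihood ratio; out-of-support proposals are rejected outright.
template <typename LL>
static double rw_step(double cur, double lo, double hi, AdaptScale& sc,
                      LL loglik, double ll_cur, double& ll_out) {
  const double prop = cur + std::exp(sc.ls) * norm_rand();
  bool accepted = false;
  double ll_new = ll_cur;
  if (prop > lo && prop < hi) {
    const double ll_prop = loglik(prop);
    if (std::log(unif_rand()) < ll_prop - ll_cur) {
      accepted = true;
      ll_new = ll_prop;
    }
  }
  sc.tally(accepted);
  ll_out = ll_new;
  return accepted ? prop : cur;
}

// Metropolis-within-Gibbs chain for the known-boundary (BITS) model.
// Sweep: conjugate mu, conjugate beta per phase, RW Metropolis on sigma and
// rho (adapted during warmup only), then record. Returns n_keep x 7:
// beta1, beta2, mu1, mu2, sigma, rho, es.
// [[Rcpp::export]]
NumericMatrix run_bits_chain_cpp(NumericVector yb, NumericVector yt,
                                 List prior, NumericVector init,
                                 int n_warmup, int n_keep,
                                 int adapt_interval, double target_accept) {
  const double beta_prec = prior["beta_prec"];
  const double mu_mean = prior["mu_mean"];
  const double mu_prec = prior["mu_prec"];
  const double sig_lo = prior["sigma_low"], sig_hi = prior["sigma_high"];
  const double rho_lo = prior["rho_low"], rho_hi = prior["rho_high"];

  double b1 = init[0], b2 = init[1], mu1 = init[2], mu2 = init[3];
  double sigma = init[4], rho = init[5];

  AdaptScale sc_sigma(std::log(0.3), target_accept);
  AdaptScale sc_rho(std::log(0.5), target_accept);
  NumericMatrix out(n_keep, 7);

  const double mu_post_prec = mu_prec + beta_prec;
  const double mu_post_sd = 1.0 / std::sqrt(mu_post_prec);

  double ll = bits_loglik_cpp(yb, yt, b1, b2, sigma, rho);
  check_finite(ll);

  const int total = n_warmup + n_keep;
  for (int it = 0; it < total; ++it) {
    // mu | beta: conjugate normal-normal
    mu1 = (mu_prec * mu_mean + beta_prec * b1) / mu_post_prec +
          mu_post_sd * norm_rand();
    mu2 = (mu_prec * mu_mean + beta_prec * b2) / mu_post_prec +
          mu_post_sd * norm_rand();
    // beta | rest: conjugate, independent across phases
    {
      NumericVector fc1 = beta_fc_bits_cpp(yb, rho, sigma, beta_prec, mu1);
      b1 = fc1[0] + fc1[1] * norm_rand();
      NumericVector fc2 = beta_fc_bits_cpp(yt, rho, sigma, beta_prec, mu2);
      b2 = fc2[0] + fc2[1] * norm_rand();
      ll = bits_loglik_cpp(yb, yt, b1, b2, sigma, rho);
      check_finite(ll);
    }
    // sigma, rho: adaptive random-walk Metropolis
    sigma = rw_step(sigma, sig_lo, sig_hi, sc_sigma, [&](double s) {
      return bits_loglik_cpp(yb, yt, b1, b2, s, rho);
    }, ll, ll);
    rho = rw_step(rho, rho_lo, rho_hi, sc_rho, [&](double r) {
      return bits_loglik_cpp(yb, yt, b1, b2, sigma, r);
    }, ll, ll);

    const bool warm = it < n_warmup;
    if (warm && (it + 1) % adapt_interval == 0) {
      sc_sigma.adapt();
      sc_rho.adapt();
    }
    if (!warm) {
      const int k = it - n_warmup;
      out(k, 0) = b1; out(k, 1) = b2; out(k, 2) = mu1; out(k, 3) = mu2;
      out(k, 4) = sigma; out(k, 5) = rho;
      out(k, 6) = (b1 - b2) / sigma;
    }
  }
  return out;
}

// Chain for the unknown change-point model. Adds an exact categorical Gibbs
// update of CP over {cp_min..cp_max} with log prior weights logw.
// Returns n_keep x 8: beta1, beta2, mu1, mu2, sigma, rho, CP, es.
// [[Rcpp::export]]
NumericMatrix run_bucp_chain_cpp(NumericVector y, List prior,
                                 NumericVector init, int cp_min, int cp_max,
                                 NumericVector logw, int n_warmup, int n_keep,
                                 int adapt_interval, double target_accept) {
  const double beta_prec = prior["beta_prec"];
  const double mu_mean = prior["mu_mean"];
  const double mu_prec = prior["mu_prec"];
  const double sig_lo = prior["sigma_low"], sig_hi = prior["sigma_high"];
  const double rho_lo = prior["rho_low"], rho_hi = prior["rho_high"];

  double b1 = init[0], b2 = init[1], mu1 = init[2], mu2 = init[3];
  double sigma = init[4], rho = init[5];
  int cp = int(init[6]);

  const int n_cp = cp_max - cp_min + 1;
  std::vector<double> lp(n_cp), pr(n_cp);

  AdaptScale sc_sigma(std::log(0.3), target_accept);
  AdaptScale sc_rho(std::log(0.5), target_accept);
  NumericMatrix out(n_keep, 8);

  const double mu_post_prec = mu_prec + beta_prec;
  const double mu_post_sd = 1.0 / std::sqrt(mu_post_prec);

  double ll = bucp_loglik_cpp(y, cp, b1, b2, sigma, rho);
  check_finite(ll);

  const int total = n_warmup + n_keep;
  for (int it = 0; it < total; ++it) {
    mu1 = (mu_prec * mu_mean + beta_prec * b1) / mu_post_prec +
          mu_post_sd * norm_rand();
    mu2 = (mu_prec * mu_mean + beta_prec * b2) / mu_post_prec +
          mu_post_sd * norm_rand();
    // joint conjugate (b1, b2) given CP, rho, sigma
    {
      List fc = beta_fc_bucp_cpp(y, cp, rho, sigma, beta_prec, mu1, mu2);
      NumericVector m = fc["mean"];
      NumericMatrix cv = fc["cov"];
      const double l11 = std::sqrt(cv(0, 0));
      const double l21 = cv(1, 0) / l11;
      const double l22 = std::sqrt(cv(1, 1) - l21 * l21);
      const double u1 = norm_rand(), u2 = norm_rand();
      b1 = m[0] + l11 * u1;
      b2 = m[1] + l21 * u1 + l22 * u2;
      ll = bucp_loglik_cpp(y, cp, b1, b2, sigma, rho);
      check_finite(ll);
    }
    sigma = rw_step(sigma, sig_lo, sig_hi, sc_sigma, [&](double s) {
      return bucp_loglik_cpp(y, cp, b1, b2, s, rho);
    }, ll, ll);
    rho = rw_step(rho, rho_lo, rho_hi, sc_rho, [&](double r) {
      return bucp_loglik_cpp(y, cp, b1, b2, sigma, r);
    }, ll, ll);
    // CP | rest: exact categorical full conditional
    {
      double mx = R_NegInf;
      for (int j = 0; j < n_cp; ++j) {
        lp[j] = bucp_loglik_cpp(y, cp_min + j, b1, b2, sigma, rho) + logw[j];
        if (lp[j] > mx) mx = lp[j];
      }
      double tot = 0;
      for (int j = 0; j < n_cp; ++j) { pr[j] = std::exp(lp[j] - mx); tot += pr[j]; }
      double u = unif_rand() * tot, cum = 0;
      int pick = n_cp - 1;
      for (int j = 0; j < n_cp; ++j) {
        cum += pr[j];
        if (u <= cum) { pick = j; break; }
      }
      cp = cp_min + pick;
      ll = lp[pick] - logw[pick];
    }

    const bool warm = it < n_warmup;
    if (warm && (it + 1) % adapt_interval == 0) {
      sc_sigma.adapt();
      sc_rho.adapt();
    }
    if (!warm) {
      const int k = it - n_warmup;
      out(k, 0) = b1; out(k, 1) = b2; out(k, 2) = mu1; out(k, 3) = mu2;
      out(k, 4) = sigma; out(k, 5) = rho; out(k, 6) = cp;
      out(k, 7) = (b1 - b2) / sigma;
    }
  }
  return out;
}
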