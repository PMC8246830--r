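---
title: "Bayesian interrupted time-series and change-point models for single-case designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian interrupted time-series and change-point models for single-case designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scedbayes)
```

## The problem

Single-case experimental designs record one participant repeatedly across a
baseline phase and a treatment phase. The resulting series are short (often
five to eight points per phase) and serially dependent, which defeats the
standard toolkit: OLS assumes independence, and both OLS and ML interval
estimates of the lag-1 autocorrelation undercover severely at these lengths.
Bayesian estimation handles the small-sample, autocorrelated setting
naturally, and its credible intervals admit direct probability statements —
the quantity a clinician actually wants ("how sure are we the effect exceeds
half an SD?").

`scedbayes` implements the two models described below, a native MCMC sampler
for them, the convergence diagnostics and posterior summaries needed to
report a fit, a synthetic-data generator for calibration studies, and a small
CLI.

## Models and assumptions

Let `y_t`, `t = 1..T`, be the outcome with the baseline phase first,
`T_b` baseline and `T_t` treatment points. Both models are intercept-only
within phase — no trend terms — with AR(1) Gaussian errors shared across
phases:

* **BITS** (known boundary). Each phase `p` is its own chain: the first
  observation of the phase is `N(β_p1, σ_ε²)` and subsequent ones are
  `N(β_p1 + ρ(y_{t−1} − β_p1), σ_ε²)`. The conditioning restarts at the
  boundary: both phase-opening observations are unconditional. This mirrors a
  model statement that declares the first observation of each phase
  separately.
* **BUCP** (unknown boundary). One unbroken chain over all `T` points with a
  step-function mean `μ_t = β₁₁` for `t ≤ CP` and `β₂₁` after, where the
  change point `CP` is the index of the *last* baseline-governed observation.
  Only `y_1` is unconditional; in particular the first post-change
  observation is conditioned on the last pre-change one. There is no second
  unconditional observation because there is no known second segment.

Assumptions worth stating plainly: Gaussian innovations on an interval-scaled
outcome; a single shared `ρ` (conventional for these designs); level shift
only (no slope change); equally spaced consecutive integer time steps.

Two conventions were genuinely open and are fixed as follows. First, the
first observation of a chain uses the innovation SD `σ_ε`, not the stationary
SD `σ_ε/√(1−ρ²)`; this mirrors the model statement exactly and matters
only at very small `T`. Second, `CP` means "last baseline index", so the true
change point for a `6 + 6` series is 6; the support is `{4, …, T−3}` because
three points are needed to establish a pattern on either side (a series needs
`T ≥ 7` before the change-point model is estimable at all).

The AR(1) white-noise identity `σ_e = σ_ε√(1−ρ²)` is exposed as the
reporting utility `white_noise_sd()`; it plays no role in the likelihood,
which Equations of the conditional form above specify completely.

## Priors

Defaults (`prior_spec()`):

| parameter | prior | default | why |
|---|---|---|---|
| `β_p1` | `N(μ_p, 1/beta_prec)` | `beta_prec = 1` | weakly informative at the outcome scale |
| `μ_p` | `N(mu_mean, 1/mu_prec)` | `N(5, 20)` | hyperprior; variance 20 flattens the prior so the data dominate; 5 is mid-scale for a 1–7 outcome |
| `σ_ε` | `U(sigma_low, sigma_high)` | `U(0.1, 5)` | covers any plausible innovation SD for a bounded scale |
| `ρ` | `U(rho_low, rho_high)` | `U(−1, 1)` | agnostic about direction and strength of serial dependence |
| `CP` | `Categorical(cp_weights)` | uniform on `{4..T−3}` | the support is stated; no weights are, so uniform |

The hierarchical β-prior ("a prior on a prior") is deliberately pessimistic
about prior influence. `log_prior()` returns `-Inf` outside the support
rather than raising, so Metropolis steps can simply reject.

## Sampler

`fit_sced()` runs Metropolis-within-Gibbs (compiled, `src/sampler.cpp`). One
sweep:

1. `μ₁, μ₂` — exact conjugate normal-normal updates given `β`.
2. `β₁₁, β₂₁` — exact conjugate updates: quasi-differencing
   `y_t − ρ y_{t−1}` makes the model linear-Gaussian in `β` given
   `(ρ, σ_ε, CP)`. For BITS the phases decouple; for BUCP the design row at
   the change point couples the two intercepts, so the update is jointly
   bivariate.
3. `σ_ε`, `ρ` — random-walk Metropolis on the natural scale; out-of-support
   proposals are rejected (the uniform prior cancels inside the support, so
   the ratio is a pure likelihood ratio). Proposal scales adapt toward an
   acceptance rate of 0.44 during warm-up only (batches of 50, Robbins-Monro
   step `min(0.5, 2/√batch)`), then freeze so the retained chain is
   Markovian.
4. `CP` (BUCP) — exact categorical Gibbs: the likelihood is evaluated at
   every admissible change point and the normalized full conditional sampled
   directly. `cp_full_conditional()` exposes this distribution.

Defaults follow the reference workflow: 4 chains, 1,000 adaptation + 5,000
burn-in sweeps discarded, 30,000 retained draws per chain, starting values
drawn independently from the prior (dispersed starts are what give the
between-chain diagnostics their teeth). Per-chain seeds derive
deterministically from one master seed. The effect size
`es = (β₁₁ − β₂₁)/σ_ε` is appended draw-wise, so posterior uncertainty in all
three quantities propagates into it; this is why no small-sample correction
factor is applied to `es`.

The sampler is validated two independent ways in the test suite: the
conditional likelihood against a joint multivariate-normal oracle whose
covariance is built from the AR recursion (agreement to 1e−8 or better on
random instances), and the conjugate full conditionals against generalized
least squares with that same covariance. During development the full
posterior was additionally checked against quadrature over
`(σ_ε, ρ, CP)` with `β` integrated analytically; sampler and quadrature agree
to Monte-Carlo error.

## Convergence diagnostics

* `psrf()` — Gelman–Rubin: `R̂ = sqrt(((n−1)/n · W + B/n)/W)`.
* `mpsrf()` — Brooks–Gelman: `(n−1)/n + ((m+1)/m)·λ₁` with `λ₁` the largest
  eigenvalue of `W⁻¹B/n`. Note this is on the squared-PSRF scale; it bounds
  the squared univariate factor of every linear combination.
* `heidelberger_welch()` — per chain: a Cramér–von Mises test on the
  standardized cumulative-sum process, with the long-run variance `S(0)`
  estimated from the second half of the chain by an AR approximation (order
  by AIC, capped at 10 — `spectrum0_ar()`); on rejection the initial 10% is
  discarded and the test repeated up to 50%. The halfwidth test passes when
  `z_{0.975}·sqrt(S(0)/n)` is within 10% of the absolute mean.

Numerical choices: the four-term Bessel series for the Cramér–von Mises CDF
is accurate at the operating quantiles (0.90/0.95/0.99 at 0.347/0.461/0.743)
but decays spuriously for very large statistics, so it is clamped to 1 for
`q ≥ 3`; without the clamp a wildly nonstationary chain could pass. A
constant chain passes both tests trivially with halfwidth 0. The integer
`CP` is excluded from PSRF/MPSRF (discreteness and near-rank-deficiency break
the normal-theory variance decomposition) and is instead assessed by the
maximum total-variation distance between per-chain `CP` frequency tables,
flagged at 0.05. `convergence_report()` flags `converged` at
PSRF, MPSRF < 1.1 — reported, never enforced; the CLI signals it via exit
status 2 instead of auto-extending chains, keeping runtimes deterministic.

Known limitation: with the AR-based `S(0)` estimator, a steep deterministic
trend drives the fitted AR toward a unit root, inflating `S(0)` and shrinking
the test statistic; the untrimmed chain is still rejected, but a trimmed
trending chain can be accepted. Trend-plus-noise chains at realistic
signal-to-noise ratios are rejected at every trim fraction, which is what
the tests assert.

## Posterior summaries

`summarize_posterior()` pools chains (combine-then-summarize) and reports
2.5%/50%/97.5% quantiles (type-7 linear interpolation, fixed), mean, and SD
(denominator `n−1`), in the reporting order `CP` (BUCP only), `β₁₁`, `β₂₁`,
`σ`, `ρ`, `es`. Whether a published 95% interval is equal-tailed or
highest-density is often unstated, so both are available: `interval = "hdi"`
uses the narrowest-window estimator (`hdi()`: smallest span of
`⌈mass·n⌉` consecutive sorted draws). Comparisons against reference values in
the acceptance tests use means and medians only, which are
interval-convention-free.

`rope_fraction()` reports the share of effect-size draws strictly above
`comp_val − rope_rad`, the smallest effect the analyst would accept as
practically meaningful. `immediacy()` is the median of the last three
baseline minus the median of the first three treatment observations —
descriptive, with no accepted interpretation thresholds, so none are
provided. `cp_mode_and_table()` breaks ties toward the smaller change point
(reported behaviour, chosen so a tie never overstates how late the effect
began).

## Synthetic data and what a green test establishes

`simulate_sced()` runs the AR(1) recursion forward under known parameters;
`ar_restart` selects the BITS convention (default) or the continuous-chain
BUCP convention, so each model can be exercised under well-specified data.
First observations use the innovation SD, matching the models. Defaults
(`β = 5/2`, `σ_ε = 1`, `ρ = 0.2`, `T_b = T_t = 10`) encode the regime these
models are recommended for: at least eight points per phase and a
standardized separation of about 3, where published simulation work finds
estimation reasonably accurate. `recovery_study()` wraps the
simulate-fit-summarize loop and reports bias, RMSE, interval coverage, and
the modal-change-point hit rate.

The generator emulates level-shifted AR(1) Gaussian series only. It does not
produce trends, count or bounded-scale censoring effects, missingness, or
phase-specific autocorrelation — so a green recovery test establishes
correctness of the estimation machinery under the model's own assumptions,
not robustness to their violation.

The acceptance suite (tests/testthat/test-acceptance.R) checks: the worked
example's immediacy (1.01) and its BITS posterior against published reference
summaries at stated tolerances; change-point recovery on the worked example;
likelihood-vs-MVN-oracle agreement at 1e−8; a 20-replication recovery study
(coverage of β within the binomial band around 0.95, change-point hit rate);
and insensitivity of posterior means to halving/doubling the hyperprior
variance (10/20/40). One reference value is asserted and left failing
deliberately: the published change-point-model effect-size mean (2.65) is not
reproducible from the model as specified here — exact quadrature with the
intercepts integrated analytically gives ≈ 1.98 for these priors, matching
the sampler, and that published row is arithmetically inconsistent with its
own intercept and σ rows under the draw-wise effect-size definition. The
test documents rather than hides the discrepancy.

## Degenerate inputs and edge cases

Phases need ≥ 3 finite observations (hard error) and ≥ 8 for comfortable
estimation (warning). `NA` cells in input files pad the shorter phase and are
stripped, never stored. The change-point model refuses series with `T < 7`
(empty support). Constant chains pass Heidelberger–Welch trivially; an
all-equal series yields a uniform change-point full conditional (the
likelihood is flat in `CP`). Out-of-support states have prior density zero,
not an exception, so samplers and optimizers can probe freely.
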