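Package: scedbayes
Title: Bayesian Interrupted Time-Series and Unknown Change-Point Models for
    Single-Case Experimental Designs
Version: 0.1.0
Authors@R:
    person("Sam", "Ellis", email = "sellis@example.org",
           role = c("aut", "cre"))
Description: Fits Bayesian interrupted time-series (BITS) and Bayesian
    unknown change-point (BUCP) models to short, autocorrelated two-phase
    single-case experimental design (SCED) series via a native
    Metropolis-within-Gibbs sampler. Provides convergence diagnostics
    (univariate and multivariate potential scale reduction factors,
    Heidelberger-Welch stationarity and halfwidth tests), posterior
    summaries with equal-tailed and highest-density intervals, a
    standardized mean difference effect size with region-of-practical-
    equivalence reporting, an immediacy statistic, a synthetic AR(1)
    SCED generator for parameter-recovery studies, plotting utilities,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
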