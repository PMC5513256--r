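Package: richsplit
Title: Sample Splitting for Nonparametric Species Richness Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Improves nonparametric species-richness estimation under
    constrained sampling by randomly splitting a single species-abundance
    sample into k equally sized sub-samples and applying an incidence-based
    estimator (bias-corrected Chao2, incidence Jackknife, ICE) to the
    resulting presence/absence data, aggregated over repeated random splits.
    Includes the classical abundance-based estimators (bias-corrected Chao1,
    abundance Jackknife orders 1-2, ACE), ranked catch-probability models for
    lognormal, log-series, geometric-series and negative-binomial
    species-abundance distributions, a Monte Carlo harness that scores every
    estimator by mean-squared error over simulated assemblages, and tools to
    extract the critical sample-size-to-richness thresholds that decide when
    the splitting method should be preferred and which estimator to use.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
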