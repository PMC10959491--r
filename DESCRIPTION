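Package: thermoqg
Title: Pedigree-Based Quantitative Genetics of Thermoregulatory Capacity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating selection on, and genetic variation in,
    thermoregulatory capacity measured by infrared thermal imaging in
    pedigreed populations. Provides pedigree validation and additive
    relationship matrices (tabular method, Henderson sparse inverse),
    preprocessing of thermal-image and hourly-weather records into
    model-ready observations (per-day cubic-spline air temperature,
    head-neck surface-temperature deviation, temperature-change reaction-norm
    covariates), a Gibbs-sampling engine for Bayesian linear mixed models
    with Gaussian and binary-liability (threshold) responses, unstructured
    covariance random terms optionally linked to a relationship matrix and
    heterogeneous residuals, posterior summaries (kernel-density mode, HPD
    intervals, pMCMC, convergence diagnostics), repeatability, heritability,
    evolvability and genetic correlations computed draw-wise from variance
    components, declarative model recipes for reaction-norm, category and
    threshold selection analyses, and a seeded synthetic-data generator
    with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
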