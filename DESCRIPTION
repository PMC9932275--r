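Package: idex
Title: Explainable Consensus Classification of Invasive Disease Events
Version: 0.1.0
Authors@R: person("IDEX", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An explainable machine-learning pipeline for predicting breast
    cancer invasive disease events (IDE) from mixed-type clinical features.
    Implements an iterative multi-classifier consensus procedure that flags
    label-inconsistent ("confounding") patients, Boruta-style shadow-feature
    selection with nested selection frequencies, repeated stratified
    cross-validation of four classifier families (random forest, RBF support
    vector machine, gradient boosted trees, Gaussian naive Bayes) under a
    prevalence-derived decision threshold, and a from-scratch Shapley-value
    explanation layer (exact coalition enumeration and a kernel-weighted
    linear surrogate) producing global and per-patient attributions. A
    synthetic-cohort generator with planted confounders stands in for the
    private clinical dataset so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
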