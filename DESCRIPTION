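Package: firthint
Title: Firth-Corrected Cox Interaction Models and Simulation-Based Power
    for Small Biomarker Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying and planning small survival studies of
    predictive biomarkers, where a Cox proportional hazards model with a
    multiplicative marker-treatment interaction term is the standard
    analysis.  Provides a synthetic-data generator (multinomial assignment
    to four marker-treatment cells with given margins and odds ratio,
    exponential event and censoring times, administrative censoring), a
    from-scratch Cox partial-likelihood estimator with optional Firth
    penalization, Wald and profile-likelihood confidence intervals and
    tests, Monte-Carlo performance measures (bias, standard-error accuracy,
    coverage, type I error and power), and a scenario runner and
    simulation-based power calculator for marker-treatment interaction
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
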