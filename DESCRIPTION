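Package: survsig
Title: Survival-Supervised Two-Metagene Expression Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building and evaluating prognostic gene-expression
    classifiers for right-censored outcomes. Probes are screened by
    multivariate Cox proportional-hazards regression adjusted for clinical
    covariates, selection is stabilised by leave-one-out cross-validation,
    and a continuous prognostic index is computed from the first two
    principal components of percentile-ranked expression over the selected
    probes. Includes chip-level quality control, reference-set median
    centering, Kaplan-Meier and log-rank evaluation, multi-site replicate
    reproducibility analysis, and a synthetic-cohort generator for testing.
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
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
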