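Package: septikit
Title: Gene-Expression Ratio Classifiers and Diagnostic Evaluation for
    Sepsis Host-Response Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building and evaluating additive two-ratio
    gene-expression classifiers that discriminate sepsis from
    infection-negative systemic inflammation in critically ill patients.
    Covers discovery (univariate prefilter, exhaustive two-gene ratio AUC
    screen, greedy ratio-pair search), RT-qPCR scoring of the four-gene
    PLAC8/PLA2G7/LAMP1/CEACAM4 panel into a quantitative score with
    likelihood-ratio bands and Bayesian post-test probabilities, and the
    full diagnostic comparison apparatus: empirical and binormal ROC
    curves, stratified bootstrap AUC intervals, DeLong and Venkatraman
    tests, 2x2 contingency metrics with likelihood ratios, net
    reclassification indices, distribution comparisons, a binomial cohort
    balance check, and forward greedy logistic combination of clinical
    covariates under repeated cross-validation. A seeded synthetic-cohort
    generator makes every component testable without access to patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
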