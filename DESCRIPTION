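Package: phthalret
Title: Design-Based Association Analysis of Urinary Phthalate Metabolites
    and Diabetic Retinopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reusable pipeline for studying the association of
    urinary phthalate metabolite concentrations with self-reported diabetic
    eye affliction/retinopathy in complex-survey cohorts such as NHANES.
    Implements limit-of-detection substitution, creatinine dilution correction
    with rank-based inverse normal transformation, pseudo-maximum-likelihood
    logistic regression with stratified between-PSU (Taylor-linearized)
    sandwich variance, Bonferroni-corrected multi-metabolite scans, nested
    multivariable models, validation of a self-reported outcome against an
    imaging gold standard (Cohen's kappa), a Monte Carlo outcome-
    misclassification sensitivity analysis, and a Cochran-Armitage
    dose-response trend test. A synthetic cohort generator with known ground
    truth (survey design, correlated log-normal exposures with censoring at
    the limit of detection, logistic outcome model, self-report
    misclassification) makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
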