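Package: cohortrisk
Title: Multi-Cohort Clinical Risk Model Development and Internal Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and internally validating clinical risk
    prediction models on clustered multi-cohort binary-outcome data, with
    an application profile modeled on multi-center prostate biopsy
    consortia. Implements five fitting/prediction strategies for clustered
    data (pooled logistic regression, random-intercept logistic regression
    with median or mean prediction, and fixed- or random-effects two-stage
    meta-analysis of per-center coefficients), validation metrics (AUC with
    DeLong intervals, Hosmer-Lemeshow calibration, decision-curve net
    benefit with bootstrap intervals), exhaustive cohort-level
    cross-validation with leave-one-cohort-out and designated-cohort
    exclusion influence analyses, a synthetic multi-cohort generator with
    known ground truth, and cohort-heterogeneity visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    pracma,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
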