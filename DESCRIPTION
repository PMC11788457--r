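Package: ctgperf
Title: Outcome-Based Performance Evaluation of Computerized Antepartum CTG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for evaluating a binary computerized
    cardiotocography (CTG) classification (such as the Dawes-Redman
    "criteria met" / "criteria not met" call) against term pregnancy
    outcomes. Provides a synthetic subject-level cohort generator with
    configurable confounding and test operating characteristics,
    eligibility rules that build normal-outcome (NPO) and adverse-outcome
    (APO) cohorts with per-rule audit trails, 1:1 caliper-constrained
    propensity-score matching with covariate balance diagnostics,
    prevalence-standardized diagnostic performance metrics with
    logit-method (Mercaldo) confidence intervals for predictive values,
    time-window and per-outcome stratified reports, and conditional
    logistic regression on matched pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
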