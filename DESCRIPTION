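Package: wardwatch
Title: Predicting Unplanned ICU Transfers from Ward Event Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for modelling unplanned transfers from the
    inpatient floor to the intensive care unit. Provides a seeded synthetic
    electronic-health-record generator (multi-unit encounters, irregularly
    sampled vitals, sparse labs, integer acuity scores, nursing-assessment
    attribute-value pairs, intervention events), heuristic case/control cohort
    construction with matched control sampling, time-windowed sparse feature
    extraction from irregular clinical time series, elastic-net logistic
    regression and dropout-regularised multilayer perceptrons trained by
    stochastic gradient ascent on the penalized log-likelihood, and a
    prediction-horizon evaluation harness (Mann-Whitney auROC, DeLong
    confidence intervals and tests, specificity at fixed sensitivity, and
    prevalence-adjusted positive predictive value).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    Matrix,
    pROC,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
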