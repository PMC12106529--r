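Package: mesothresh
Title: Threshold Dose-Response Models for Asbestos-Induced Mesothelioma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for estimating exposure thresholds in the dose-response
    relationship between asbestiform mineral fibres and malignant
    mesothelioma, from occupational cohort summary data. Implements a
    conceptual three-factor excess-risk model, a Monte Carlo
    threshold-classification simulation of linear excess-mortality fits,
    a threshold-extended Peto lifetime-risk model for exposure intensity
    and duration, the Schaeffer "filter" (quadratic-in-log-dose survival)
    model with its inflection-point threshold, and cross-mineral threshold
    extrapolation by mesothelioma potency ratios. Ships the six non-textile
    chrysotile cohort summaries used throughout as a built-in table, and a
    synthetic-cohort generator for parameter-recovery testing.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
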