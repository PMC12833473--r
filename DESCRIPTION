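Package: hdpstools
Title: High-Dimensional Propensity Score Workflows for Healthcare Code Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-dimensional propensity score (HDPS) analyses of
    longitudinal healthcare-code data: assessment-window handling for
    long-format code dimensions (diagnoses, prescriptions, laboratory tests),
    candidate-feature identification with code aggregation and prevalence
    filtering, recurrence-based binary covariate generation, Bross-formula
    covariate prioritisation with zero-cell correction and instrument-like
    covariate flagging, logistic propensity score estimation with stabilised
    trimmed inverse probability of treatment weights, weighted Cox outcome
    models with robust variance, covariate-balance and propensity-overlap
    diagnostics, and a synthetic claims-like cohort generator with known
    ground truth for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
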