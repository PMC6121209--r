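Package: ichscores
Title: Admission Prognostic Scores and ROC Evaluation for Primary
    Intracerebral Hemorrhage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes admission prognostic scores for primary intracerebral
    hemorrhage (the ICH score, the New ICH score, and a Modified New ICH
    score that substitutes the Modified Rankin Scale for the NIHSS), ABC/2
    hematoma volume estimation, and a complete diagnostic-evaluation engine
    for ordinal scores against 30-day mortality: stratified mortality,
    empirical ROC curves, tie-corrected AUC, cutoff metrics (sensitivity,
    specificity, predictive values, likelihood ratios, Youden J) and
    Youden-optimal cutoff selection.  Includes a synthetic-cohort generator
    calibrated to a published score-outcome distribution so every stage is
    testable without patient data, and a small pipeline (simulate, score,
    evaluate) with a command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tidyselect,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
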