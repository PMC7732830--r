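Package: painbalance
Title: Simulation and Multilevel Mediation Analysis of the Pain-Performance Trade-Off
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the trial-by-trial trade-off between thermal
    pain perception and concurrent working-memory performance. Provides a
    synthetic cohort generator (individualized thermal psychophysics,
    adaptive n-back difficulty calibration, trait questionnaires with
    realistic intercorrelations), stimulus-response curve fitting with
    correction for site-specific habituation and site-nonspecific
    sensitization, the non-parametric signal-detection statistic A with a
    staircase difficulty calibrator, two multilevel mediation models (pain
    interference and task analgesia) with bias-corrected bootstrap inference
    and second-level trait moderation, and group-level descriptive summaries.
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
    minpack.lm,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
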