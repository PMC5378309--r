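Package: cbatt
Title: Adaptive Biomarker Threshold Designs for Single-Arm Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Design, simulation and analysis of single-arm two-stage trials
    that adaptively update a continuous biomarker recruitment threshold at an
    interim analysis. The biomarker-response relationship is modelled on the
    quantile scale with logistic regression, the response rate of the
    enriched subpopulation is available in closed form, and the stage-two
    recruitment threshold is chosen by beta-binomial predictive power.
    Provides the binomial exact test for final efficacy analysis, estimation
    of the biomarker threshold defining the responsive subpopulation with
    resampling intervals, exact and Monte-Carlo operating characteristics
    (type-I error, power, stopping rates, screening burden), and an
    application workflow for retrospective subject-level data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
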