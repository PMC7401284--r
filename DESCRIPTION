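Package: fpmiron
Title: Food Pattern Modeling Versus Mean Intake Estimates for Iron Status
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating food pattern modeling (FPM), a portion-free
    dietary assessment that scores a diet by the fraction of consumed foods
    with high nutrient density, against conventional mean dietary intake
    estimates (MIE) from multi-day 24 h recalls. Computes per-participant
    iron, ascorbic acid, phytate and phytate-iron (molar or mass) ratio
    variables from item-level recall records and a food composition table;
    runs a diagnostic-accuracy protocol (quartile dichotomisation, biomarker
    cutoff grids, 2x2 confusion tables, Fisher's exact tests, ROC curves,
    paired method comparison) against hemoglobin, ferritin and acute iron
    absorption; and simulates complete synthetic cohorts with a configurable
    diet-biomarker association so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    purrr,
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
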