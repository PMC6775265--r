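Package: pvror
Title: Pharmacovigilance Signal Detection for Hemorrhagic Adverse Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for disproportionality analysis of
    spontaneous adverse-event reports: ingestion of FAERS-style quarterly
    ASCII tables and a canonical CSV schema, case-version deduplication,
    MedDRA-style event definitions from SMQ-by-SOC preferred-term
    intersections, crude and age-stratified reporting odds ratios with Wald
    confidence intervals and a signal criterion, covariate-adjusted reporting
    odds ratios from a stepwise multiple logistic model with interaction
    terms selected by likelihood-ratio tests, and Weibull time-to-onset
    analysis with hazard-profile classification. Ships a synthetic
    individual-case-safety-report generator with a ground-truth ledger so
    every stage can be validated against known effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    ggplot2,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
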