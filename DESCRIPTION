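Package: pvsignal
Title: Pharmacovigilance Signal Detection and Characterization for
    Spontaneous-Report Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for disproportionality analysis of
    FAERS-style spontaneous adverse-event reports: ingestion of quarterly
    delimited tables, text normalization, case-version deduplication,
    primary-suspect/serious-event cohort construction at the MedDRA
    Preferred Term level, four disproportionality statistics (reporting
    odds ratio, proportional reporting ratio, Bayesian information
    component, and the empirical Bayes geometric mean from a two-gamma
    mixture gamma-Poisson shrinker) with standard signal criteria and
    stratified analyses, hierarchical time-to-onset derivation with
    rank-based group comparison, and clinical characterization tables.
    Includes a synthetic report generator with planted signals so every
    stage is testable without access to the live database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
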