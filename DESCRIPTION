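Package: statindili
Title: Disproportionality Analysis of Statin-Associated Drug-Induced Liver
    Injury in Spontaneous Reporting Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance signal detection of
    drug-induced liver injury (DILI) associated with statins in FAERS-style
    spontaneous-report databases. Reads the quarterly "$"-delimited DEMO,
    DRUG, REAC, OUTC and THER tables, deduplicates report versions by the
    FDA-recommended latest-receipt-date rule, standardizes drug names to the
    eight statin generics, builds the DILI cohort from a narrow-scope
    hepatic-disorders MedDRA query term list, and computes reporting odds
    ratios and Bayesian information components with dual signal criteria,
    age-stratified variants, demographic and outcome rollups, dose-trend and
    time-to-onset analyses. Includes a synthetic five-table database
    generator with planted association structure and an exact truth ledger
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
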