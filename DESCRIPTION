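Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Report Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for pharmacovigilance disproportionality
    analysis of FDA Adverse Event Reporting System (FAERS) quarterly data
    extracts and synthetic equivalents. Parses the dollar-delimited
    DEMO/DRUG/REAC/OUTC table layout, deduplicates multi-version individual
    case safety reports by retaining the most recent case version, cohorts a
    target primary-suspect drug, and screens adverse events at the MedDRA
    preferred-term and system-organ-class level using the reporting odds ratio
    (ROR) with exact-formula 95% confidence intervals and the Bayesian
    information component (IC) with closed-form 95% credibility bounds.
    Includes a combination-therapy comparator analysis for immune checkpoint
    inhibitor co-exposure, a Table-1-style demographics summariser, and a
    seeded synthetic-data generator that plants drug-event associations of
    known strength so every stage of the pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
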