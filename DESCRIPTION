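Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for pharmacovigilance disproportionality
    analysis of FAERS-style spontaneous adverse-event report databases: a synthetic
    report generator with planted drug-event reporting-odds effects and configurable
    duplicate/invalid contamination; curation (drug-name normalization, structural
    validation, case deduplication); suspect-role-aware case selection over MedDRA
    preferred terms; 2x2 contingency construction; and a multitiered signal
    framework combining the reporting odds ratio with Woolf confidence intervals,
    Fisher exact p-values, proportional and relative reporting ratios,
    continuity-corrected chi-square, the Evans criteria, and the Bayesian
    information component with its IC025 credibility bound.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
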