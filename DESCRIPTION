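Package: srsignal
Title: Disproportionality Signal Detection and Onset Modeling for
    Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance pipeline for spontaneous
    reporting system (SRS) data in the FAERS and JADER dialects: report
    ingestion, deduplication and primary-suspect filtering; per-event 2x2
    contingency tables against a rest-of-database comparator; four
    disproportionality algorithms (reporting odds ratio, proportional
    reporting ratio, BCPNN information component, and the empirical-Bayes
    gamma-Poisson shrinker) combined under a four-way consensus rule with
    Bonferroni control; sex-stratified subgroup odds ratios; and
    time-to-onset analysis with Kaplan-Meier curves and Weibull hazard
    classification. A synthetic-report generator with recorded ground
    truth makes every stage testable without access to the source
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
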