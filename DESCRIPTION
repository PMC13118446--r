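Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for pharmacovigilance signal detection
    on FAERS-dialect spontaneous-report tables: quarterly ASCII ingestion,
    case-level deduplication and cohort cleaning, dual-background 2x2
    contingency construction at the (report, preferred-term) pair level, four
    disproportionality statistics (reporting odds ratio, proportional
    reporting ratio, MHRA chi-square rule, BCPNN information component) with
    an all-method consensus rule, case-noncase logistic regression with
    confounder adjustment, composable sensitivity re-analyses, and a
    synthetic report generator with analytically known ground truth for
    end-to-end validation. Includes a closed-form inversion oracle that
    reconstructs 2x2 tables from published (count, ROR, PRR, PRR lower limit)
    tuples so printed results can be checked without the source data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
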