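Package: ragcscreen
Title: Screening and Classification of RTK-Amplified Gastric Cancers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for identifying receptor-tyrosine-kinase
    (RTK) amplified advanced gastric cancers from routine pathology readings.
    Converts immunohistochemistry scores (EGFR, HER2, MET, mismatch-repair
    proteins, p53), EBER in situ hybridization readings, and per-nucleus
    silver in situ hybridization (SISH) signal counts into categorical marker
    calls; assigns each tumor to surrogate molecular subgroups under two
    rule-based classification systems (putative-molecular and
    histologic-molecular); applies a triage decision tree that routes cases to
    immunotherapy evaluation, HER2- or RTK-targeted therapy work-up, or target
    sequencing; and computes the screening sensitivity/specificity,
    association, and Kaplan-Meier/log-rank survival statistics used to compare
    the two systems. Includes a deterministic count-table expander and a
    seeded stochastic cohort and SISH-signal simulator so the whole pipeline
    is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
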