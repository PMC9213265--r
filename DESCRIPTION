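Package: opicohort
Title: Opioid Prescription Episodes, Ordinal Cohorts, and Many-to-One
    Comparisons from Claims Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pharmacoepidemiological analysis of long-term,
    high-dose opioid prescription in cancer patients from claims-style
    tabular data. Builds continuous prescription episodes under a
    configurable persistence gap, converts doses to oral morphine
    equivalents, classifies patients into an ordered control / case I /
    case II cohort, extracts covariates over pre-index and on-episode
    windows, summarises rescue-medication use, and provides Dunnett and
    Steel many-to-one comparisons plus proportional-odds ordinal
    regression with a two-step variable-selection filter. A synthetic
    claims generator with planted ground truth makes the whole pipeline
    testable without access to any proprietary database.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    mvtnorm,
    readr,
    stats,
    tibble
Suggests:
    MASS,
    multcomp,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
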