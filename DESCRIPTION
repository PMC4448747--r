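Package: promtime
Title: Time-Resolved Promiscuity Analysis of Bioactive Compound Records
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying how the promiscuity of bioactive compounds
    (the number of distinct targets a compound is annotated against)
    progresses over time in ChEMBL-like bioactivity databases. Provides
    validated delimited-text input of compound-target-assay activity
    records, confidence-tiered record filtering (strict direct-assay
    Ki/IC50 criteria versus permissive human single-protein criteria),
    annual growth tables for compounds, targets, assays and activity
    records, per-compound cumulative distinct-target time courses with
    delta-promiscuity histograms and debut-year cohort summaries, and a
    seeded generator of synthetic longitudinal activity data with known
    ground truth for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
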