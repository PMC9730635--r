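Package: condemnr
Title: Condemnation Surveillance Indices for Poultry Slaughter Inspection Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing monthly post-mortem condemnation records from
    poultry slaughterhouses: the Condemnation Occurrence Index (COI, condemnations
    per million head slaughtered), the ratio-to-annual-mean Adjusted Seasonal
    Index (ASI), cause-frequency accounting with a technological/non-technological
    taxonomy, comparison of species-mix month groups (Welch t test with
    rank-biserial and point-biserial effect sizes), Spearman correlation between
    condemnation causes with Mukaka strength grading, per-calendar-month
    inference (one-way ANOVA with Tukey HSD, one-sample t tests against the
    annual expectation), and a seeded Poisson/negative-binomial generator of
    synthetic monthly slaughter series for validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    ggplot2,
    yaml,
    rlang,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
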