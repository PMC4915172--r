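Package: srsignal
Title: Signal Detection and Time-to-Onset Analysis for Spontaneous
    Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pharmacovigilance analysis of spontaneous
    reporting system databases in the four-table JADER schema (demo,
    drug, reac, hist): report ingestion and complete-case filtering,
    crude reporting odds ratios with Woolf confidence intervals and
    signal classification, age- gender- and reporting-year-adjusted
    reporting odds ratios via logistic regression with likelihood
    ratio tests (whole database and drug subsets), Weibull
    time-to-onset analysis with hazard-shape classification, and a
    synthetic-database generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    stringi,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    optparse
Config/testthat/edition: 3
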