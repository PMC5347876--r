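Package: eicare
Title: A Clinically Adaptive Measure of Engagement in Outpatient HIV Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies every month of a person's HIV outpatient follow-up as
    "in care" or "out of care" using a time-updated rule table that maps the
    clinical state at each attended care episode (CD4 count and its change,
    viral load and blip status, treatment events, recency of diagnosis) to the
    number of months within which the next attendance is expected. Includes
    delimited-text cohort ingestion using laboratory results and therapy dates
    as surrogate attendance markers, person-month analytics with stratified
    engagement summaries and a generalized-estimating-equations logistic model
    for within-patient correlated months, and a seeded synthetic-cohort
    simulator with known ground-truth engagement for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
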