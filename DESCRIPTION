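Package: pddialert
Title: Drug-Drug Interaction Fax-Alert Programs: Detection, Matched-Cohort
    Evaluation, and Claims Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating prescriber-directed potential drug-drug
    interaction (PDDI) alert programs run on pharmacy claims. Provides a
    machine-readable rulebank of clinically important interacting drug
    pairs with recommended therapeutic alternatives, a nightly-scan style
    detection engine that finds concurrent-exposure episodes and attributes
    alerts to the prescriber of the second interacting drug, 1:1 matched
    control cohort construction (age, gender, line of business, time
    period), 90-day therapy-change outcome ascertainment, per-pair and
    pooled contingency-table inference with expected-cell-count driven
    test selection, a covariate-adjusted logistic model of change
    (including a medication-based comorbidity proxy), and a synthetic
    pharmacy-claims generator with recorded ground truth so the whole
    pipeline is testable without protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
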