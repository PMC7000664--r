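Package: isend
Title: iSEND Prognostic Score Analysis for NSCLC Immunotherapy Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the iSEND clinical risk score (sex, ECOG performance
    status, baseline neutrophil-to-lymphocyte ratio and its on-treatment
    change) for advanced non-small-cell lung cancer patients on PD-1/PD-L1
    monotherapy, and runs the full downstream analysis: cohort validation
    and exclusion cascades, Kaplan-Meier estimation with log-log confidence
    bands, reverse Kaplan-Meier follow-up, log-rank tests, multivariate Cox
    proportional hazards models, time-dependent positive and negative
    predictive values of binary prognostic markers under right censoring
    with a paired bootstrap comparison test, cohort-comparison table
    statistics, and a calibrated synthetic-cohort generator so every
    pipeline stage is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
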