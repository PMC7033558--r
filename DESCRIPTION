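Package: handrace
Title: Racing Hand-Posture Simulators for Visual Laterality Judgement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates visual hand-laterality judgements with racing
    drift-diffusion "hand posture simulators": each hand is represented by a
    two-boundary diffusion process with a start-point bias and a stochastic
    quit-timer that forces a reject decision when it elapses. Two simulators
    race in two-handed observers; a single simulator models people born with
    one hand. Includes grid-search fitting of group-level accuracy and mean
    reaction time, the accompanying behavioural analysis pipeline (trial
    filtering, log-RT trimming, easy/hard difficulty assignment, signal
    detection indices, motor-task and prosthesis-usage scores), rank
    correlation utilities with a test for the difference between two dependent
    correlations, and a synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    rlang,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
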