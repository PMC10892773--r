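Package: pdmil
Title: Weakly Supervised Severity Staging of Parkinson's Disease from
    Wearable Inertial Sensor Recordings
Version: 0.1.0
Authors@R:
    person("pdmil", "developers", email = "pdmil@example.org",
           role = c("aut", "cre"))
Description: A multiple-instance-learning pipeline for staging Parkinson's
    disease severity (healthy/mild/moderate/severe) from wrist-worn
    tri-axial accelerometer and gyroscope recordings carrying only
    subject-level labels.  Recordings are bandpass filtered, z-scored and
    sliced into fixed 1.5 s windows; each window is summarised by nine
    time-domain statistics, quantised against per-activity k-means
    codebooks into symbolic "words", and each subject's chronological word
    sequence is treated as a document.  A latent Dirichlet allocation
    topic model supplies global per-subject topic features that are fused
    with the word-count histogram for subject-level leave-one-out
    classification.  Class imbalance is addressed by bag-level
    augmentation: Hamming-similar same-class document pairs are crossed
    position-wise and instance order is shuffled within activities.
    Includes a synthetic-cohort generator with severity-graded intermittent
    tremor and bradykinesia that stands in for clinical data in all tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    matrixStats,
    quadprog,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
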