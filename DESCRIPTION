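Package: emgdx
Title: Needle Electromyography Diagnosis Classification with Segment-Level
    Deep Learning and Divide-and-Vote Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, classification and evaluation pipeline for
    diagnosis-aiding analysis of needle electromyography (nEMG) signals.
    Generates synthetic cohorts of motor unit action potential (MUAP)
    trains with class-conditional physiology for myopathy, neuropathy and
    normal muscle, persists them as WAV + manifest cohorts, resamples and
    segments the signals, trains a compact 1-D residual convolutional
    network on 0.4-second segments, aggregates segment predictions to
    signal- and patient-level diagnoses by divide-and-vote majority, and
    evaluates the pipeline with nested 5x3-fold patient-level
    cross-validation, one-vs-rest multiclass metrics, rank-based
    comparison against a simulated physician rater panel, consensus and
    failure analysis, and activation-maximization feature visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
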