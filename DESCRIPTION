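Package: thetanav
Title: Theta-Gamma Phase-Amplitude Coupling Analysis for Goal-Directed
    Navigation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for hippocampal-formation virtual-channel
    signals recorded during abstract grid-navigation tasks: Morlet
    time-frequency power, theta band power, mean-vector-length theta-gamma
    phase-amplitude coupling with trial-wise power residualization, and the
    standard confound controls (aperiodic 1/f slope, evoked-response
    amplitude, oscillation waveform asymmetry). Includes a task simulator
    for the 4x4 abstract navigation paradigm (shortest-path combinatorics,
    novelty and tortuosity bookkeeping) and a synthetic-signal generator
    implementing the theta-gamma sequence-coding model, so that every stage
    of the pipeline can be validated by parameter recovery. Group-level
    inference follows the trial-wise regression plus one-sample t-test
    convention.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, TimeCourse, Electrophysiology, StatisticalMethod
RoxygenNote: 7.3.3
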