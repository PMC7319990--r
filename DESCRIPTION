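Package: revroc
Title: ROC-Based Stimulus Selectivity of Cortical Neurons Across Reversal Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing trial-structured two-photon calcium imaging
    recorded during Go/No-go texture discrimination and reversal learning.
    Provides trace preprocessing (neuropil correction, per-trial detrending,
    dF/F0 normalisation, nonnegative AR(1) spike inference, response-onset
    estimation), behavioural scoring and rolling performance curves with an
    expert-criterion and learning-onset detector, ROC-based discrimination and
    choice indices with permutation significance, phase-resolved neuron
    classification (gained/lost/remained/reversed; choice versus value),
    random-forest decoding of whisking and licking rates from time-lagged
    inferred firing rates calibrated against an activity-independent control
    channel, and an outcome-history-conditioned response statistic (error
    history) with permutation confidence bounds. A synthetic-session generator
    with ground-truth neuron classes supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
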