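Package: emgdec
Title: Continuous EMG Decoding for Myoelectric Prosthesis Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for continuous (regression-style) decoding of
    multichannel surface electromyography into prosthesis kinematics.
    Implements causal EMG preprocessing and mean-absolute-value feature
    extraction with differential channel expansion, mimicry-training
    protocol generation (trapezoidal single- and combination-movement
    trials), temporal feature/kinematic alignment and stepwise
    Gram-Schmidt feature selection, three continuous decoders (a
    threshold-modified Kalman filter, a two-hidden-layer tanh multilayer
    perceptron, and a temporal convolutional network), a recursive
    nonlinear latching filter for output smoothing, a simultaneity
    statistic for decoded kinematic traces, per-participant statistical
    comparison plans, and a seeded synergy-based synthetic-EMG simulator
    so the full train/decode/analyze pipeline can be exercised without
    human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
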