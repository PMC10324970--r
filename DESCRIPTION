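Package: semgkit
Title: Surface EMG Finger-Movement Classification Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature-extraction and classification strategies for multichannel
    surface electromyography (sEMG) gesture recognition: dynamic causality
    graphs with graph-entropy features; local tangent space alignment and
    local linear coordination manifold reduction feeding a restricted
    Boltzmann machine stack with an extreme learning machine output layer and
    particle swarm topology search; empirical wavelet transform band
    decomposition with differential entropy and high-order fuzzy cognitive
    map features; and local mean decomposition with fuzzy C-means encoding
    and a convex hybrid-kernel least-squares support vector machine. Includes
    a synthetic multichannel sEMG generator with controllable class-dependent
    causal coupling, band-limited spectra and amplitude envelopes, plus a
    cross-validated benchmarking harness with sensitivity, specificity,
    accuracy and detection-rate reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    class,
    rpart,
    signal
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    withr,
    jsonlite
Config/testthat/edition: 3
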