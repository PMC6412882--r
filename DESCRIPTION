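Package: rehabrec
Title: Sensor-Based Rehabilitation Exercise Recognition and Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognition and quality evaluation of rehabilitation exercises
    from triaxial accelerometer recordings. Implements symbolic
    state-transition features via two-pass Lempel-Ziv-Welch coding and
    probabilistic finite state automata, Gaussian mixture regression
    trajectory models with Mahalanobis-based dynamic channel assignment, a
    family of multipath one-dimensional convolutional networks (gravity/body,
    state-transition, dynamic and fused variants) trained with stochastic
    gradient descent, and an LSTM-based evaluation framework that learns
    per-class general features and scores exercise quality on a bounded
    cosine-derived scale. Includes a synthetic recording generator emulating
    repeated exercises at graded quality levels, repetition segmentation by
    autocorrelation peak analysis, and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    mclust,
    pracma,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
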