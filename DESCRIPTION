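Package: rteeg
Title: EEG Emotion Recognition for Reminiscence-Therapy Conversations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying positive and negative affect from
    multichannel electroencephalography (EEG) recorded during
    photograph-prompted reminiscence conversations with older adults.
    Provides a synthetic cohort generator with band-structured EEG
    (1/f background, theta/alpha/beta oscillations, mains interference,
    baseline drift and a configurable lateralized alpha-asymmetry class
    effect), pleasure/stress and valence-arousal rating-to-label schemes,
    Butterworth band-pass and Chebyshev type-I high-pass preprocessing,
    3-second trial segmentation, and LSTM / bidirectional-LSTM sequence
    classifiers trained with k-fold cross-validation, early stopping and
    an optimizer/learning-rate grid. The recurrent network engine
    (forward pass and backpropagation through time) is implemented in
    C++ via RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    signal,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
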