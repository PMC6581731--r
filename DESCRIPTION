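Package: eegemo
Title: Emotion Recognition from Multi-Channel EEG via Linear Autoencoder
    Source Decomposition and LSTM Sequence Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dimensional emotion recognition from multi-channel
    scalp EEG. Implements a linear stacked autoencoder that solves the
    linear scalp-mixing model X = AS and emits latent source signals,
    frame-wise frequency-band-power and inter-channel Pearson-correlation
    feature sequences (1 s Hanning windows, 50 percent overlap, Welch
    power spectral density), and a long short-term memory (LSTM) plus
    fully-connected classifier over 125-frame feature sequences with
    sigmoid output. Includes a synthetic EEG generator with known mixing
    ground truth and ratings coupled to source band-power dynamics,
    High/Low labeling with class balancing, k-fold cross-validation with
    paired significance tests, and HDF5 input/output for trial sets,
    feature sequences and model checkpoints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    rhdf5,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
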