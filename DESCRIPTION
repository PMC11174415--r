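Package: sogpcn
Title: Self-Organizing Graph Pseudo-3D Convolutional Networks for EEG
    Emotion Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a self-organizing graph pseudo-3D convolutional
    network (SOGPCN) for emotion recognition from multichannel EEG
    differential-entropy features. A learned, input-dependent adjacency
    matrix is built per frequency band and sparsified by top-k selection;
    graph convolution extracts spatial features, factorized (pseudo-3D)
    spatiotemporal convolution with partial dot-product attention extracts
    temporal features, and a peephole LSTM with a softmax head classifies
    trials into negative, neutral and positive emotion. Includes
    differential-entropy feature extraction from raw EEG, a synthetic
    SEED-like dataset generator with planted class structure, and an
    experiment harness for leave-one-subject-out and subject-dependent
    cross-validation, band/channel/top-k sweeps and ablations.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
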