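Package: emognn
Title: Trial-Wise EEG Emotion Classification with Task-Specific
    Connectivity Graphs and Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Binary classification of multichannel EEG trials using a
    temporal-spatial attention network built on task-specific
    functional-connectivity graphs.  Channels are encoded into log-power
    node features by parallel multi-scale temporal convolutions with
    kernel attention; a pair of class-conditioned adjacency matrices
    (correlation, coherence, phase locking value, or phase lag index) is
    estimated from training data and drives a two-stage graph convolution
    with adjacency attention; per-graph features are fused by a cascaded
    classifier.  Includes band-pass filtering and overlapping-window
    segmentation, EDF reading and writing, a synthetic EEG generator with
    planted class-dependent phase coupling, and a stratified trial-wise
    nested cross-validation protocol with early stopping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
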