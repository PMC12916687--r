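Package: msgm
Title: Multi-Scale Spatiotemporal Graph State-Space Models for EEG Emotion Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Subject-independent EEG emotion classification with a multi-scale
    spatiotemporal graph architecture. Extracts relative power spectral density
    features over seven canonical frequency bands from two-level multi-window
    segmentations, initialises bimodal (whole-scalp and within-region) channel
    graphs from hybrid correlation/distance statistics, encodes them with
    multi-depth Chebyshev graph convolutions, fuses token embeddings, and models
    temporal dynamics with a selective state-space (Mamba-style) block stack.
    Includes a leave-one-subject-out training and evaluation harness on a small
    reverse-mode automatic differentiation engine, Welch t-test / Cohen's d
    comparison utilities, and a synthetic band-limited EEG generator so the full
    pipeline is testable without access to licensed EEG corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
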