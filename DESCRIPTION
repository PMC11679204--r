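Package: mitransfer
Title: Multi-Subject Transfer Learning for Motor-Imagery EEG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for four-class motor-imagery EEG classification with
    multi-subject transfer learning. Provides dual-branch attention
    convolutional networks (FCNNA, XFCNN, LFCNN variants) with a flat layer
    registry supporting freeze-by-index fine-tuning, genetic-algorithm
    channel selection over the 22-channel 10-20 montage,
    leave-one-subject-out pre-training on source subjects, and an online
    session-divided prequential retraining protocol for target subjects.
    Includes a synthetic EEG generator emulating event-related
    desynchronization over class-specific channel subsets with 1/f
    background noise and per-subject spatial mixing, parameter and
    multiply-accumulate accounting for all network variants, and a minimal
    GDF reader/writer for cue-annotated recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
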