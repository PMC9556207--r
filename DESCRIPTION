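Package: bcimusic
Title: EEG Music-Feedback Pipeline for Depression Neurofeedback
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested implementation of a closed-loop brain-computer-interface
    music-therapy pipeline for mild depression: seeded synthetic EEG sessions
    with ground-truth emotion states and artifact contamination, denoising by
    empirical mode decomposition (EMD), FastICA and their combination with
    signal-to-noise improvement (SNIR), mean-energy and MAPE quality metrics,
    a from-scratch convolutional network and a logistic gradient-boosting
    classifier for 0.5-second emotion windows, conversion of classified state
    sequences into 6-second music-feedback segments, and scoring, severity
    banding and independent t-test summaries for the SCL-90, SDS and PHQ-9
    depression scales.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
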