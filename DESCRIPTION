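Package: wearstress
Title: Multimodal Stress Detection from Intermittent Wearable Physiological Signals
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying ordinal stress levels
    (low/medium/high) from intermittently collected multirate wearable
    recordings (tri-axial accelerometer, electrodermal activity, heart rate,
    skin temperature). Provides gap-based work-session segmentation,
    overlapping fixed-length windowing, Gaussian-jitter augmentation,
    dual-domain feature extraction (sub-frame time statistics and binned
    log-magnitude spectra), from-scratch SMOTE class rebalancing, a parallel
    two-branch one-dimensional convolutional network with late feature
    fusion (implemented natively, including backpropagation and Adam),
    ablation variants, evaluation reports, grid-search and
    expected-improvement hyperparameter tuning, and a synthetic multirate
    signal generator with designed class-separability structure so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
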