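Package: ppgaf
Title: Atrial Fibrillation Detection from Photoplethysmography with
    Compact Deep Classifiers and Premature-Atrial-Complex Handling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to detect atrial fibrillation (AF) from single-channel
    photoplethysmography (PPG). Provides a synthetic cohort generator that
    emulates paired pre- and post-cardioversion recordings (the post-
    cardioversion sinus rhythm carrying premature atrial complexes, PACs,
    at controlled burden), the standard conditioning pipeline (bias
    removal, 0.2-18 Hz zero-phase band-pass, per-window normalisation,
    30-s segmentation with 20-s overlap), pulse-peak detection with an
    inter-beat-interval PAC indicator (85 percent rule) and burden
    computation, linear-kernel SVM baselines on RMSSD, Shannon entropy and
    autocorrelation features, compact 1-D convolutional and recurrent
    softmax classifiers trained by backpropagation with a confidence-level
    metric, and evaluation machinery: patient-wise and sample-wise 5-fold
    cross-validation, diagnostic rates, ROC/AUC with the DeLong test for
    correlated curves, PAC-burden-stratified specificity, and
    confidence-level calibration analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    graphics
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
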