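Package: ledpatnet
Title: S-Box Textural Features, Tunable Q-Factor Wavelets and Hybrid
    Feature Selection for EEG Emotion Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Channel-wise EEG emotion recognition with hand-crafted
    features. Implements the Led-Pattern, a nonlinear one-dimensional
    textural descriptor that compares each sample of a 16-sample
    overlapping window against the position designated by the 4-bit
    S-box of the LED block cipher and histograms the resulting 8-bit
    codes; a 14-component statistical moment vector; a tunable Q-factor
    wavelet transform (TQWT) with perfect reconstruction for multilevel
    decomposition; the fused 540-feature-per-signal / 10,260-feature
    extractor over the raw frame and 18 sub-bands; the RFIChi2 hybrid
    feature selector (ReliefF pruning of negative-weight features
    followed by an iterative chi-square-ranked sweep scored by
    cross-validated SVM loss); and cubic (degree-3 polynomial kernel)
    SVM ten-fold cross-validated evaluation with confusion-matrix
    metrics. Includes a synthetic EEG generator with class-dependent
    band-power structure plus plain-text dataset readers, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
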