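Package: mvfcm
Title: Entropy-Regularized Multiview Fuzzy C-Means for EEG Seizure Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiview fuzzy c-means clustering with entropy-regularized view
    weighting, and a clustering-based classifier for seizure versus non-seizure
    EEG segments. Includes construction of three EEG views (raw time series,
    4-30 Hz Fourier magnitudes, and level-6 wavelet-packet subband envelopes),
    optional per-view convolutional feature extractors, seeded synthetic data
    generators for multiview Gaussian clusters and seizure-like EEG segments,
    evaluation metrics, and JSON model persistence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
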