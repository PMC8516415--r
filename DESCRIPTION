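Package: somnostage
Title: Automated Sleep Staging from Polysomnography with Gradient-Boosted Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Feature-based automatic sleep staging for polysomnography (PSG)
    recordings. Extracts time-domain and spectral features from EEG, EOG and
    EMG signals in 30-second epochs, adds temporal-context smoothing and
    per-night normalization, and classifies the five AASM sleep stages
    (W, N1, N2, N3, R) with a class-weighted gradient-boosted tree model that
    reports per-epoch stage probabilities and confidence. Includes consensus
    scoring across multiple human scorers with reliability-based tie-breaking,
    epoch-by-epoch agreement metrics (accuracy, Cohen's kappa, Matthews
    correlation, per-stage F1), EDF input/output, and a reproducible synthetic
    PSG generator for end-to-end validation without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    xgboost,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
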