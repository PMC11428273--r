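Package: boldcast
Title: Frequency-Specific Adversarial Forecasting of BOLD Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasting and prolongation of region-averaged BOLD (fMRI) time
    series. Decomposes each regional signal into band-limited intrinsic mode
    functions by variational mode decomposition (ADMM in the frequency
    domain), selects the low-frequency modes that carry the stable functional
    connectome, and forecasts each mode with an adversarially trained
    GRU encoder-decoder equipped with dual (temporal and spatial) attention
    built on convolutional block attention modules. Training minimises a
    hybrid objective combining a per-window Euclidean error, a sign-based
    trend term, a distribution-matching term and a sigmoid cross-entropy
    adversarial term. Includes sliding-window construction with max-min
    normalisation, chronological splitting, forecast metrics (RMSE, MAE,
    dynamic time warping), test-retest reliability of functional
    connectivity via per-edge intraclass correlation with Cicchetti grading,
    a synthetic cohort generator for end-to-end validation, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
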