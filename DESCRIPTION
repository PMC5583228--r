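Package: wmentropy
Title: Spectral-Entropy Biomarkers of Working-Memory Performance from EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating EEG spectral entropy to working-memory
    performance in delayed-match-to-sample experiments. Scores behavior with
    the Signed Residual Time (SRT) speed-accuracy trade-off rule, extracts
    normalized spectral entropy (base-10, "dit") from Welch power spectra of
    retention-period epochs, maps channel-wise Spearman correlations between
    entropy and SRT with false-discovery-rate control, classifies high versus
    low performers with a linear support vector machine under leave-one-out
    cross-validation, predicts SRT with radial-basis support vector
    regression, and quantifies training-induced change-rate consistency.
    Includes a seeded synthetic cohort generator (colored-noise EEG with a
    latent ability coupling spectral uniformity to behavior) so the full
    pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
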