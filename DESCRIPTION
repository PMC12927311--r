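Package: efrchirp
Title: Chirp-Based Auditory Envelope-Following Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for gamma-range auditory envelope-following
    responses (EFR) to chirp-like click-train stimulation (30-60 Hz).
    Builds the chirp frequency-to-time mapping, decomposes epoched EEG with
    complex Morlet wavelets, computes the inter-trial phase-locking index
    (PLI) and event-related spectral perturbation (ERSP) with relative
    baseline normalization, extracts per-frequency response curves,
    individual gamma frequencies (IGF) and laterality indices over
    fronto-central regions of interest, and runs the accompanying
    nonparametric group statistics (Wilcoxon rank-sum and signed-rank tests
    with Bonferroni correction, Spearman correlations, chi-square test of
    independence). Includes a synthetic-EEG cohort generator with
    controllable phase locking (von Mises concentration), response
    amplitude, resonance frequency and 1/f background noise, so the full
    pipeline can be exercised and validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
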