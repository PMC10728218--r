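Package: eegopt
Title: Spectral and Temporal Filter Optimization for Resting-State EEG
    Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting binary clinical outcomes (seizure-free vs
    non-seizure-free) from resting-state multichannel EEG by searching a grid
    of narrow spectral bands and temporal window lengths. Implements the full
    pipeline: seeded synthetic two-group EEG cohorts with planted band-limited
    transient effects, EDF input/output, epoching/re-referencing/zero-phase
    bandpass preprocessing, nine time-domain feature families (Hjorth,
    statistical moments, energy, zero crossings, inter-channel correlation and
    phase-locking connectivity with graph summaries, Fourier, Stockwell and
    wavelet spectra), four analysis strategies (no search, optimal frequency,
    optimal time, optimal frequency-and-time) evaluated with nested
    cross-validated classification, plus group-comparison effect sizes and
    channel-topology similarity statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    utils,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    ranger,
    rlang,
    signal,
    stats,
    tibble,
    tidyr
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
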