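Package: cycleshape
Title: Single-Cycle Waveform Shape of Neural Oscillations via Masked EMD
    and Phase-Aligned Instantaneous Frequency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the nonsinusoidal waveform shape of single
    oscillatory cycles in continuous electrophysiological recordings.
    Oscillations are isolated with a masked empirical mode decomposition
    (mask sift with monotone PCHIP envelopes), instantaneous phase,
    frequency and amplitude are estimated with the Hilbert transform,
    and individual cycles are detected, quality-controlled and described
    by control-point ratios. Within-cycle instantaneous frequency is
    phase-aligned onto a uniform 48-point phase grid so cycles of
    different durations can be compared; normalized unit-amplitude
    waveforms, a complex mean-vector shape statistic, PCA-derived shape
    motifs with split-half stability, and permutation-tested ordinary
    least squares models of motif scores against per-cycle covariates
    complete the framework. Simulation generators (schematic cycles,
    autoregressive oscillators, quadratic nonlinearities, dynamic-shape
    signals with known categories) are included so the whole pipeline is
    testable without data downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
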