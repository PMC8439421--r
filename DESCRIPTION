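Package: boldlin
Title: Voxel-Wise Linearity Analysis of BOLD Signal Increments and Decrements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test the superposition (linearity) property of BOLD
    fMRI responses at the single-voxel level using a contrast adaptation
    paradigm. Includes a synthetic-data generator for event-related
    contrast-adaptation and block-design localizer runs (two-gamma HRF
    forward model with controllable nonlinearity, drift and white noise),
    the preprocessing chain (percent signal change, Fourier band-pass and
    component-indexed high-pass filtering, trial recombination and
    averaging into 25-s measured responses), activated-voxel selection via
    finite-impulse-response deconvolution r-squared with permutation null
    distributions and FDR correction, superposition predictions scored by
    a signed amplitude-sensitive Dice index with permutation chance
    thresholds, bounded two-gamma HRF fitting with contrast-index deviation
    analysis, and FFT-based signal-to-noise-ratio grouping with
    nonparametric comparisons.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    lhs,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
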