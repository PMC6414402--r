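Package: physiodr
Title: Frequency-Domain Physiological Modelling of Fast-TR fMRI by Iterative Dual Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models single-voxel power spectra of fast repetition-time (TR)
    echo planar imaging (EPI) resting-state fMRI as a general linear model of
    a constant thermal-noise baseline plus cardiac and respiratory amplitude
    spectra, and refines the physiological regressors by an iterative dual
    regression along the spatial and frequency dimensions.  Initial regressor
    spectra come either from externally recorded pulse-oximetry and
    respiratory-belt traces ("informed" mode) or from a band split of the EPI
    spectrum itself ("data-driven" mode).  Fitted parameter-estimate maps are
    summarized into partial-volume-weighted mean coefficients, spatial-extent
    ratios, mask overlaps and a windowed cardiac pulsatility metric, with
    covariate-controlled partial correlation for group analyses.  Includes a
    synthetic fast-TR EPI generator with known ground truth for validation,
    NIfTI input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
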