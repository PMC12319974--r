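Package: mebold
Title: Multi-Echo BOLD fMRI Simulation, Thermal Denoising, Optimal Echo
    Combination, and Reliability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for precision functional mapping with multi-echo BOLD fMRI
    on volumetric grids. Implements patch-based low-rank (NORDIC-style)
    thermal-noise removal of complex-valued echo series, voxelwise
    monoexponential T2* and S0 mapping with T2*-weighted optimal echo
    combination, framewise-displacement motion quality control with
    respiratory band-stop filtering of motion parameters, 36-parameter
    nuisance regression with censored-frame interpolation and band-pass
    filtering, dense and parcellated functional connectivity, temporal
    signal-to-noise ratio and autocorrelation-based smoothness metrics, and
    permuted split-half reliability curves. A synthetic multi-echo BOLD
    generator with age-specific tissue presets (adult, child, infant T2*
    distributions), known network covariance, physiological noise, and
    motion traces provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
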