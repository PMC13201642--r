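Package: wmhkit
Title: White Matter Hyperintensity Segmentation Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classical computational stack for white-matter-hyperintensity
    (WMH) segmentation in brain MRI: tissue-statistics-driven intensity
    standardization with piecewise linear rescaling, median/Gaussian
    denoising and z-score + min-max normalization; adaptive-threshold
    candidate lesion detection with 3-D morphological refinement; blockwise
    DCT image fusion with block-quality selection and consistency
    verification; a small SRCNN-style super-resolution forward pass trained
    by particle swarm optimization (PSO); a generic PSO with inertia; the
    full segmentation evaluation battery (weighted Dice loss, DSC, HD95,
    precision/recall/F1, AVD, PSNR, MSE, SSIM, UQI); and a reproducible
    synthetic brain phantom generator so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
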