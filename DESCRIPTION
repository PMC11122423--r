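Package: dssmlm
Title: Deep-Learning Reconstruction of Spectroscopic Single-Molecule
    Localization Microscopy Data
Version: 0.1.0
Authors@R:
    person("sSMLM", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation, training and reconstruction tools for spectroscopic
    single-molecule localization microscopy (sSMLM). Provides a physics-based
    simulator of paired spatial/spectral blinking frames, a compact U-Net
    emitter localizer operating on an upsampled prediction grid, a residual
    convolutional enhancer for low-photon spectral point-spread functions,
    linear spectral calibration, spectral-window filtering and multicolor
    channel assignment, cross-correlation drift correction, spectral-regression
    merging of repeated emissions, super-resolution rendering, and an
    evaluation suite (Jaccard index, lateral RMSE, SSIM, Gaussian-fit FWHM,
    Fourier ring correlation resolution). Networks are trained on simulated
    data only; no GPU or external deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
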