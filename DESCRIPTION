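Package: rldamp
Title: Compressive-Sensing Image Reconstruction by Residual-Learning
    Denoising-Based Approximate Message Passing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs grayscale images from undersampled Fourier
    (k-space) measurements with denoising-based approximate message
    passing (D-AMP).  The iteration's denoiser is a nonlocal
    residual-learning operator: similar patches are grouped by block
    matching, the singular values of each group's residual against a
    guide estimate are shrunk with adaptive Laplacian-scale-mixture
    weights updated by expectation-maximisation, and the shrunken groups
    are aggregated by overlap averaging.  Includes variable-density
    k-space mask generation, a wavelet-thresholding baseline denoiser,
    a low-rank (non-residual) ablation denoiser, PSNR/SSIM evaluation,
    synthetic phantoms and textures, and experiment-grid orchestration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
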