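Package: chaoswidow
Title: Tent-Chaos Black Widow Optimization for Medical Image Denoising
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Denoises 8-bit grayscale medical-style images by tuning the
    parameters of a fixed five-stage filter chain (Gaussian, median, mean,
    bilateral, sharpening) with a Black Widow Optimization Algorithm whose
    population is initialized from a Tent chaotic map. Includes the four
    standard noise simulators (Gaussian, salt-and-pepper, Poisson, speckle),
    full-reference quality metrics (MSE, PSNR, SSIM, ENL, EPI) with region-of-
    interest support, a synthetic phantom generator for benchmarking, and an
    ablation harness comparing the full optimizer against variants without
    chaotic initialization or sharpening.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
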