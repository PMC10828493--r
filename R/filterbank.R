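# Images are plain numeric matrices with intensities in [0, 255]; every
# public filter clips to that range on exit.

assert_image <- function(img, min_dim = 3L) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix", call. = FALSE)
  if (nrow(img) < min_dim || ncol(img) < min_dim)
    stop("image must be at least ", min_dim, "x", min_dim, call. = FALSE)
  if (any(!is.finite(img)))
    stop("image contains non-finite values", call. = FALSE)
  invisible(img)
}

clip_image <- function(img) {
  img[img < 0] <- 0
  img[img > 255] <- 255
  img
}

assert_ksize <- function(ksize) {
  if (length(ksize) != 1L || ksize < 3 || ksize %% 2 != 1)
    stop("`ksize` must be a single odd integer >= 3", call. = FALSE)
  as.integer(ksize)
}

#' Normalized Gaussian smoothing kernel
#'
#' Discrete isotropic Gaussian: weight at offset (x, y) is proportional to
#' `exp(-(x^2 + y^2) / (2 sigma^2))`, renormalized so the window sums to 1.
#' The kernel is maximal at the center and radially non-increasing.
#'
#' @param sigma Standard deviation in pixels (> 0).
#' @param ksize Odd window edge length (>= 3).
#' @return `ksize x ksize` numeric matrix summing to 1.
#' @export
gaussian_kernel <- function(sigma, ksize = 3L) {
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  ksize <- assert_ksize(ksize)
  r <- (ksize - 1L) / 2L
  off <- seq(-r, r)
  k <- exp(-outer(off^2, off^2, "+") / (2 * sigma^2))
  k / sum(k)
}

base_sharpen_kernel <- function() {
  matrix(c(0, -1, 0, -1, 5, -1, 0, -1, 0), 3, 3)
}

#' Gaussian filter
#'
#' Smooths by correlating with [gaussian_kernel()] under reflect padding.
#' Constant images are fixed points.
#'
#' @param img Numeric matrix in \[0, 255\].
#' @param sigma Kernel standard deviation (> 0).
#' @param ksize Odd window edge (default 3).
#' @return Filtered image, clipped to \[0, 255\].
#' @export
apply_gaussian <- function(img, sigma, ksize = 3L) {
  assert_image(img)
  clip_image(cpp_correlate2d(img, gaussian_kernel(sigma, ksize)))
}

#' Median filter
#'
#' Replaces each pixel by the median of its reflect-padded `ksize x ksize`
#' neighborhood; removes isolated impulses without blurring edges.
#'
#' @inheritParams apply_gaussian
#' @return Filtered image, clipped to \[0, 255\].
#' @export
apply_median <- function(img, ksize = 3L) {
  assert_image(img)
  clip_image(cpp_median_filter(img, assert_ksize(ksize)))
}

#' Mean (averaging) filter
#'
#' Replaces each pixel by the arithmetic mean of its reflect-padded
#' neighborhood (uniform kernel with weights `1 / ksize^2`).
#'
#' @inheritParams apply_gaussian
#' @return Filtered image, clipped to \[0, 255\].
#' @export
apply_mean <- function(img, ksize = 3L) {
  assert_image(img)
  ksize <- assert_ksize(ksize)
  clip_image(cpp_correlate2d(img, matrix(1 / ksize^2, ksize, ksize)))
}

#' Bilateral filter
#'
#' Edge-preserving smoothing: each neighbor is weighted by the product of a
#' spatial Gaussian (standard deviation `sigma_d`, pixels) and a range
#' Gaussian on the intensity difference (standard deviation `sigma_r`,
#' intensity units), and the weighted mean is normalized by the weight sum.
#'
#' @inheritParams apply_gaussian
#' @param sigma_r Range-kernel standard deviation in intensity units (> 0).
#' @param sigma_d Spatial-kernel standard deviation in pixels (> 0).
#' @return Filtered image, clipped to \[0, 255\].
#' @export
apply_bilateral <- function(img, ksize = 3L, sigma_r = 25, sigma_d = 2) {
  assert_image(img)
  if (sigma_r <= 0 || sigma_d <= 0) stop("sigmas must be > 0", call. = FALSE)
  clip_image(cpp_bilateral_filter(img, assert_ksize(ksize), sigma_r, sigma_d))
}

#' Sharpening filter
#'
#' Blends the image with its convolution by the 3x3 sharpening kernel
#' `[[0,-1,0],[-1,5,-1],[0,-1,0]]` (which sums to 1):
#' `(1 - amount) * img + amount * (img * kernel)`. `amount = 0` is the
#' identity; `amount = 1` is plain convolution with the kernel.
#'
#' @inheritParams apply_gaussian
#' @param amount Blend weight in \[0, 2\].
#' @return Filtered image, clipped to \[0, 255\].
#' @export
apply_sharpen <- function(img, amount = 1) {
  assert_image(img)
  if (!is.numeric(amount) || amount < 0 || amount > 2)
    stop("`amount` must be in [0, 2]", call. = FALSE)
  if (amount == 0) return(clip_image(img))
  sharp <- cpp_correlate2d(img, base_sharpen_kernel())
  clip_image((1 - amount) * img + amount * sharp)
}

#' Filter-chain parameters
#'
#' The decoded settings of the five-stage denoising chain. Window edges must
#' be odd and in {3, 5, 7}; standard deviations strictly positive; the
#' sharpening blend weight in \[0, 2\].
#'
#' @param gaussian_sigma,gaussian_ksize Gaussian stage: sigma (pixels) and
#'   window edge.
#' @param median_ksize Median stage window edge.
#' @param mean_ksize Mean stage window edge.
#' @param bilateral_sigma_r,bilateral_sigma_d,bilateral_ksize Bilateral stage:
#'   range sigma (intensity units), spatial sigma (pixels), window edge.
#' @param sharpen_amount Sharpening blend weight.
#' @return An object of class `"filter_chain_params"`.
#' @export
filter_chain_params <- function(gaussian_sigma = 1, gaussian_ksize = 3L,
                                median_ksize = 3L, mean_ksize = 3L,
                                bilateral_sigma_r = 25, bilateral_sigma_d = 2,
                                bilateral_ksize = 3L, sharpen_amount = 0.5) {
  p <- list(gaussian_sigma = gaussian_sigma, gaussian_ksize = as.integer(gaussian_ksize),
            median_ksize = as.integer(median_ksize), mean_ksize = as.integer(mean_ksize),
            bilateral_sigma_r = bilateral_sigma_r, bilateral_sigma_d = bilateral_sigma_d,
            bilateral_ksize = as.integer(bilateral_ksize), sharpen_amount = sharpen_amount)
  ks <- c(p$gaussian_ksize, p$median_ksize, p$mean_ksize, p$bilateral_ksize)
  if (!all(ks %in% c(3L, 5L, 7L)))
    stop("window edges must be odd and in {3, 5, 7}", call. = FALSE)
  if (p$gaussian_sigma <= 0 || p$bilateral_sigma_r <= 0 || p$bilateral_sigma_d <= 0)
    stop("standard deviations must be strictly positive", call. = FALSE)
  if (p$sharpen_amount < 0 || p$sharpen_amount > 2)
    stop("`sharpen_amount` must be in [0, 2]", call. = FALSE)
  structure(p, class = "filter_chain_params")
}

#' @export
print.filter_chain_params <- function(x, ...) {
  cat("Filter chain parameters (Gaussian -> median -> mean -> bilateral -> sharpen)\n")
  cat(sprintf("  Gaussian:  sigma = %.3f, ksize = %d\n", x$gaussian_sigma, x$gaussian_ksize))
  cat(sprintf("  Median:    ksize = %d\n", x$median_ksize))
  cat(sprintf("  Mean:      ksize = %d\n", x$mean_ksize))
  cat(sprintf("  Bilateral: sigma_r = %.2f, sigma_d = %.3f, ksize = %d\n",
              x$bilateral_sigma_r, x$bilateral_sigma_d, x$bilateral_ksize))
  cat(sprintf("  Sharpen:   amount = %.3f\n", x$sharpen_amount))
  invisible(x)
}

#' Apply the five-stage filter chain
#'
#' Applies, in fixed order: Gaussian smoothing, median, mean, bilateral, and
#' (optionally) sharpening. The order is not searched over. The stages
#' actually applied are recorded in the `"stages"` attribute of the result.
#'
#' @param img Numeric matrix in \[0, 255\].
#' @param params A [filter_chain_params()].
#' @param use_sharpen Apply the final sharpening stage? Ablation variants set
#'   this to `FALSE`.
#' @return Denoised image (clipped to \[0, 255\]) with attribute `"stages"`.
#' @export
apply_chain <- function(img, params, use_sharpen = TRUE) {
  stopifnot(inherits(params, "filter_chain_params"))
  assert_image(img)
  out <- apply_gaussian(img, params$gaussian_sigma, params$gaussian_ksize)
  out <- apply_median(out, params$median_ksize)
  out <- apply_mean(out, params$mean_ksize)
  out <- apply_bilateral(out, params$bilateral_ksize,
                         params$bilateral_sigma_r, params$bilateral_sigma_d)
  stages <- c("gaussian", "median", "mean", "bilateral")
  if (use_sharpen) {
    out <- apply_sharpen(out, params$sharpen_amount)
    stages <- c(stages, "sharpen")
  }
  structure(out, stages = stages)
}
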