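# Full-reference quality metrics with rectangular ROI support.

#' Rectangular region of interest
#'
#' Rectangles are 0-based and half-open: the ROI covers rows
#' `row0 .. row1 - 1` and columns `col0 .. col1 - 1`.
#'
#' @param row0,col0 Top-left corner (0-based, inclusive).
#' @param row1,col1 Bottom-right corner (0-based, exclusive).
#' @return An object of class `"roi"` (integer vector of length 4).
#' @export
roi <- function(row0, col0, row1, col1) {
  r <- as.integer(c(row0, col0, row1, col1))
  if (any(is.na(r)) || r[1] < 0 || r[2] < 0 || r[3] <= r[1] || r[4] <= r[2])
    stop("ROI must be non-empty with 0-based half-open corners", call. = FALSE)
  structure(r, names = c("row0", "col0", "row1", "col1"), class = "roi")
}

roi_values <- function(img, r) {
  if (r["row1"] > nrow(img) || r["col1"] > ncol(img))
    stop("ROI extends outside the image", call. = FALSE)
  img[(r["row0"] + 1L):r["row1"], (r["col0"] + 1L):r["col1"], drop = FALSE]
}

as_roi_list <- function(rois) {
  if (inherits(rois, "roi")) rois <- list(rois)
  rois <- lapply(rois, function(r) if (inherits(r, "roi")) r else do.call(roi, as.list(r)))
  if (length(rois) == 0L) stop("at least one ROI is required", call. = FALSE)
  rois
}

#' Default homogeneous-region ROIs for ENL
#'
#' Three square ROIs centered at relative positions (1/4, 1/4), (1/4, 3/4)
#' and (3/4, 1/2) of the image, following the convention of averaging the
#' equivalent number of looks over three regions.
#'
#' @param dim Image dimensions, `c(rows, cols)`.
#' @param size ROI edge length in pixels (default 32, shrunk to fit small
#'   images).
#' @return List of three [roi()] objects.
#' @export
default_enl_rois <- function(dim, size = 32L) {
  size <- min(size, floor(min(dim) / 4))
  centers <- rbind(c(1 / 4, 1 / 4), c(1 / 4, 3 / 4), c(3 / 4, 1 / 2))
  lapply(seq_len(nrow(centers)), function(i) {
    r0 <- round(centers[i, 1] * dim[1] - size / 2)
    c0 <- round(centers[i, 2] * dim[2] - size / 2)
    roi(r0, c0, r0 + size, c0 + size)
  })
}

#' Default boundary ROIs for EPI
#'
#' Four frames along the image borders, `width` pixels wide, inset by
#' `inset` pixels so the horizontal central difference is defined everywhere
#' inside them. Edge preservation is judged near the boundaries because
#' gradients in homogeneous interior regions shrink under any smoothing.
#'
#' @param dim Image dimensions, `c(rows, cols)`.
#' @param width Frame width in pixels (default 16).
#' @param inset Inset from the border in pixels (default 1).
#' @return List of four [roi()] objects (top, bottom, left, right).
#' @export
default_epi_rois <- function(dim, width = 16L, inset = 1L) {
  h <- dim[1]; w <- dim[2]
  width <- min(width, floor(min(h, w) / 4))
  list(
    roi(inset, inset, inset + width, w - inset),            # top
    roi(h - inset - width, inset, h - inset, w - inset),    # bottom
    roi(inset, inset, h - inset, inset + width),            # left
    roi(inset, w - inset - width, h - inset, w - inset)     # right
  )
}

assert_same_dim <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("images must have identical dimensions", call. = FALSE)
}

#' Mean squared error
#'
#' `sum((ref - img)^2) / (w * h)`; symmetric, zero iff the images are equal.
#'
#' @param ref,img Numeric matrices of identical dimensions.
#' @return Non-negative scalar in squared intensity units.
#' @export
mse <- function(ref, img) {
  assert_same_dim(ref, img)
  mean((ref - img)^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10((2^n_bits - 1)^2 / MSE)` in decibels; `Inf` when the images
#' are identical. Strictly decreasing in MSE.
#'
#' @inheritParams mse
#' @param n_bits Bits per sample; 8 for the usual \[0, 255\] range.
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(ref, img, n_bits = 8L) {
  m <- mse(ref, img)
  peak <- (2^n_bits - 1)^2
  if (m == 0) return(Inf)
  10 * log10(peak / m)
}

#' Structural similarity index (global form)
#'
#' Computed from whole-image means, variances and covariance:
#' `((2 mux muy + c1)(2 sxy + c2)) / ((mux^2 + muy^2 + c1)(sx^2 + sy^2 + c2))`
#' with `c1 = (k1 L)^2`, `c2 = (k2 L)^2`. This is the single-window form; no
#' sliding window is used, so the score is invariant to any identical
#' permutation of both images' pixels. Population (1/n) moments are used, and
#' `ssim(x, x)` is exactly 1.
#'
#' @inheritParams mse
#' @param k1,k2 Stability constants (defaults 0.01 and 0.03).
#' @param L Dynamic range of pixel values (255 for 8-bit).
#' @return Scalar in \[-1, 1\].
#' @export
ssim <- function(ref, img, k1 = 0.01, k2 = 0.03, L = 255) {
  assert_same_dim(ref, img)
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  mux <- mean(ref); muy <- mean(img)
  vx <- mean((ref - mux)^2)
  vy <- mean((img - muy)^2)
  cxy <- mean((ref - mux) * (img - muy))
  ((2 * mux * muy + c1) * (2 * cxy + c2)) /
    ((mux^2 + muy^2 + c1) * (vx + vy + c2))
}

#' Equivalent number of looks
#'
#' For each ROI, `mean^2 / (var + eps)` with population variance; the ROI
#' values are averaged. Higher means smoother homogeneous regions. Constant
#' ROIs do not fail: the `eps` stabilizer yields a very large finite value
#' and the ROI is flagged in the `"saturated"` attribute.
#'
#' @param img Numeric matrix.
#' @param rois List of [roi()] rectangles (default: [default_enl_rois()]).
#' @param eps Variance stabilizer (default `1e-12`).
#' @return Scalar ENL with attributes `"per_roi"` and `"saturated"`.
#' @export
enl <- function(img, rois = default_enl_rois(dim(img)), eps = 1e-12) {
  rois <- as_roi_list(rois)
  per <- vapply(rois, function(r) {
    v <- roi_values(img, r)
    mu <- mean(v)
    s2 <- mean((v - mu)^2)
    mu^2 / (s2 + eps)
  }, numeric(1))
  saturated <- vapply(rois, function(r) {
    v <- roi_values(img, r)
    mean((v - mean(v))^2) < eps
  }, logical(1))
  structure(mean(per), per_roi = per, saturated = saturated)
}

#' Edge preservation index
#'
#' Ratio of summed absolute horizontal central differences,
#' `|I(x+1, y) - I(x-1, y)|`, on the noisy image over the same sum on the
#' denoised image, pooled across the ROIs (by convention taken near the image
#' boundaries). Equals 1 when the two images are identical; values above 1
#' mean the denoised image has weaker edges than the noisy one.
#'
#' @param noisy,denoised Numeric matrices of identical dimensions.
#' @param rois List of [roi()] rectangles (default: [default_epi_rois()]).
#'   Every ROI must leave one column of margin on each side so the central
#'   difference is defined.
#' @return Scalar EPI.
#' @export
epi <- function(noisy, denoised, rois = default_epi_rois(dim(noisy))) {
  assert_same_dim(noisy, denoised)
  rois <- as_roi_list(rois)
  grad_sum <- function(img, r) {
    if (r["col0"] < 1L || r["col1"] > ncol(img) - 1L)
      stop("EPI ROI must leave a 1-column margin for the central difference",
           call. = FALSE)
    rows <- (r["row0"] + 1L):r["row1"]
    cols <- (r["col0"] + 1L):r["col1"]
    sum(abs(img[rows, cols + 1L, drop = FALSE] - img[rows, cols - 1L, drop = FALSE]))
  }
  num <- sum(vapply(rois, function(r) grad_sum(noisy, r), numeric(1)))
  den <- sum(vapply(rois, function(r) grad_sum(denoised, r), numeric(1)))
  if (den == 0)
    stop("denoised image has zero gradient on the EPI ROIs (degenerate input)",
         call. = FALSE)
  num / den
}

#' Compute all five quality metrics
#'
#' MSE, PSNR and SSIM between the clean reference and the denoised image;
#' ENL on the denoised image; EPI between the noisy and denoised images.
#'
#' @param ref Clean reference image.
#' @param noisy Noisy input image.
#' @param denoised Denoised image.
#' @param enl_rois,epi_rois ROI lists (defaults as in [enl()] / [epi()]).
#' @param n_bits Bits per sample for PSNR.
#' @return An object of class `"metrics_report"`: a list with elements
#'   `mse`, `psnr`, `ssim`, `enl`, `epi`.
#' @export
evaluate_all <- function(ref, noisy, denoised,
                         enl_rois = default_enl_rois(dim(ref)),
                         epi_rois = default_epi_rois(dim(ref)),
                         n_bits = 8L) {
  assert_same_dim(ref, noisy)
  assert_same_dim(ref, denoised)
  structure(list(
    mse = mse(ref, denoised),
    psnr = psnr(ref, denoised, n_bits),
    ssim = ssim(ref, denoised),
    enl = as.numeric(enl(denoised, enl_rois)),
    epi = epi(noisy, denoised, epi_rois)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Image quality metrics\n")
  cat(sprintf("  MSE  : %.4f\n", x$mse))
  cat(sprintf("  PSNR : %s dB\n", if (is.infinite(x$psnr)) "Inf" else sprintf("%.3f", x$psnr)))
  cat(sprintf("  SSIM : %.4f\n", x$ssim))
  cat(sprintf("  ENL  : %.4g\n", x$enl))
  cat(sprintf("  EPI  : %.4f\n", x$epi))
  invisible(x)
}
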