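# Synthetic phantoms, the four noise simulators, and grayscale image I/O.

#' Noise specification
#'
#' Parameters of the four supported noise models. Defaults match the usual
#' benchmark settings: additive Gaussian noise with standard deviation 25
#' intensity units, salt-and-pepper density 0.05 (split equally between salt
#' and pepper), multiplicative speckle variance 0.04, and Poisson noise on
#' the intensity scale with 1 photon per intensity unit.
#'
#' @param kind One of `"gaussian"`, `"salt_pepper"`, `"poisson"`,
#'   `"speckle"`.
#' @param gaussian_sigma Gaussian noise standard deviation (intensity units).
#' @param sp_density Fraction of pixels hit by salt-and-pepper noise, in
#'   (0, 1).
#' @param speckle_variance Variance of the multiplicative Gaussian factor.
#' @param poisson_scale Photons per intensity unit; larger means less noise.
#' @param seed Optional integer seed used by [add_noise()].
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(kind = c("gaussian", "salt_pepper", "poisson", "speckle"),
                       gaussian_sigma = 25, sp_density = 0.05,
                       speckle_variance = 0.04, poisson_scale = 1,
                       seed = NULL) {
  kind <- match.arg(kind)
  if (gaussian_sigma <= 0 || speckle_variance <= 0 || poisson_scale <= 0)
    stop("noise parameters must be positive", call. = FALSE)
  if (sp_density <= 0 || sp_density >= 1)
    stop("`sp_density` must be in (0, 1)", call. = FALSE)
  structure(list(kind = kind, gaussian_sigma = gaussian_sigma,
                 sp_density = sp_density, speckle_variance = speckle_variance,
                 poisson_scale = poisson_scale, seed = seed),
            class = "noise_spec")
}

#' Add noise to an image
#'
#' Deterministic under `spec$seed`: `gaussian` adds
#' `Normal(0, gaussian_sigma^2)`; `salt_pepper` sets each pixel, with total
#' probability `sp_density`, to 0 or 255 with equal probability; `poisson`
#' draws `Poisson(img * poisson_scale) / poisson_scale`; `speckle`
#' multiplies by `1 + Normal(0, speckle_variance)`. All outputs are clipped
#' to \[0, 255\] and keep the input dimensions.
#'
#' @param img Numeric matrix in \[0, 255\].
#' @param spec A [noise_spec()].
#' @return Noisy image matrix.
#' @export
add_noise <- function(img, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  assert_image(img)
  with_seed(spec$seed, {
    out <- switch(spec$kind,
      gaussian = img + rnorm(length(img), 0, spec$gaussian_sigma),
      salt_pepper = {
        u <- matrix(runif(length(img)), nrow(img))
        v <- matrix(runif(length(img)), nrow(img))
        out <- img
        hit <- u < spec$sp_density
        out[hit & v < 0.5] <- 0
        out[hit & v >= 0.5] <- 255
        out
      },
      poisson = matrix(rpois(length(img), pmax(img, 0) * spec$poisson_scale),
                       nrow(img)) / spec$poisson_scale,
      speckle = img * (1 + rnorm(length(img), 0, sqrt(spec$speckle_variance))),
      stop("unknown noise kind: ", spec$kind, call. = FALSE)
    )
    clip_image(matrix(out, nrow(img), ncol(img)))
  })
}

#' Generate a synthetic phantom image
#'
#' Deterministic test images standing in for real grayscale scans. Every
#' phantom contains at least one homogeneous region of 32x32 or larger (so
#' ENL is meaningful) and at least one step edge (so EPI is meaningful).
#'
#' * `piecewise_constant` — a background with three constant rectangles of
#'   distinct gray levels.
#' * `gradient` — strictly monotone rows: a shallow near-homogeneous ramp,
#'   a step edge at mid-image, then a steep ramp.
#' * `edges` — vertical stripes of alternating tone and increasing width.
#' * `blobs` — random soft-edged discs on a homogeneous background.
#'
#' @param kind Phantom family.
#' @param size Edge length in pixels (>= 32, default 256).
#' @param seed Integer seed controlling the random gray levels / blob
#'   layout.
#' @return `size x size` numeric matrix in \[0, 255\].
#' @export
make_phantom <- function(kind = c("piecewise_constant", "gradient", "edges", "blobs"),
                         size = 256L, seed = 1L) {
  kind <- match.arg(kind)
  if (size < 32) stop("`size` must be >= 32", call. = FALSE)
  size <- as.integer(size)
  with_seed(seed, {
    img <- switch(kind,
      piecewise_constant = {
        levels <- sample(seq(40, 220, by = 20), 4)
        img <- matrix(levels[1], size, size)
        q <- size %/% 4
        img[(q + 1):(2 * q + q), (q + 1):(2 * q)] <- levels[2]
        img[(2 * q + 1):(3 * q + q %/% 2), (2 * q + 1):(4 * q)] <- levels[3]
        img[1:(q + q %/% 2), (2 * q + 1):(3 * q)] <- levels[4]
        img
      },
      gradient = {
        # strictly monotone rows: a shallow ramp (near-homogeneous), a sharp
        # step edge at mid-image, then a steep ramp
        half <- size %/% 2
        vals <- c(seq(55, 65, length.out = half),
                  seq(185, 235, length.out = size - half))
        matrix(vals, size, size, byrow = TRUE)
      },
      edges = {
        tones <- c(40, 215)
        col_tone <- integer(size)
        w <- 2L; i <- 1L; k <- 0L
        while (i <= size) {
          col_tone[i:min(size, i + w - 1L)] <- tones[k %% 2L + 1L]
          i <- i + w; k <- k + 1L
          if (k %% 2L == 0L) w <- min(w + 2L, size %/% 4L)
        }
        matrix(col_tone, size, size, byrow = TRUE)
      },
      blobs = {
        img <- matrix(70, size, size)
        xs <- row(img); ys <- col(img)
        n_blobs <- 6L
        for (b in seq_len(n_blobs)) {
          # keep blobs in the lower-right half so a 32x32 background patch
          # in the upper-left corner stays homogeneous
          cx <- runif(1, 0.35 * size, 0.9 * size)
          cy <- runif(1, 0.35 * size, 0.9 * size)
          rad <- runif(1, 0.04 * size, 0.12 * size)
          tone <- sample(c(150, 190, 230), 1)
          img[(xs - cx)^2 + (ys - cy)^2 <= rad^2] <- tone
        }
        img
      }
    )
    clip_image(img)
  })
}

#' Read an 8-bit grayscale image
#'
#' Reads PNG (and TIFF when the `tiff` package is available), returning a
#' numeric matrix in \[0, 255\]. Multi-channel images are converted to
#' grayscale by channel averaging.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return Numeric matrix in \[0, 255\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the `tiff` package is required for TIFF input", call. = FALSE)
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1, 2), mean)
  arr * 255
}

#' Write an 8-bit grayscale image
#'
#' Quantizes by round-half-away-from-zero to 8 bits and writes PNG or TIFF.
#'
#' @param img Numeric matrix in \[0, 255\].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_image(img)
  q <- floor(clip_image(img) + 0.5) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(q, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the `tiff` package is required for TIFF output", call. = FALSE)
      tiff::writeTIFF(q, path, bits.per.sample = 8L)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}
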