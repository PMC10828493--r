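#' Fit a denoising filter chain by Black Widow optimization
#'
#' The main fitting function. Searches the eight-dimensional parameter space
#' of the fixed five-stage filter chain (Gaussian, median, mean, bilateral,
#' sharpening) for the setting that best restores `noisy` toward the clean
#' `reference`, minimizing
#' `lambda * (1 - SSIM) + (1 - lambda) * MSE / 255^2`. Returns a classed fit
#' with the usual accessors: [coef()] gives the decoded filter parameters,
#' [fitted()] the denoised image, [predict()] applies the fitted chain to a
#' new image, [residuals()] the reference-minus-denoised error map, and
#' `plot()` the convergence history.
#'
#' @param noisy Noisy image (numeric matrix in \[0, 255\]).
#' @param reference Clean reference image of identical dimensions (tuning
#'   requires a reference; blind denoising is out of scope).
#' @param config A [bwoa_config()].
#' @param bounds A [bwoa_bounds()] over the 8 chain dimensions.
#' @param seed Integer seed; all randomness (chaotic seed draw, movement,
#'   perturbation, replacement) flows from it.
#' @param enl_rois,epi_rois ROI lists for the report metrics (defaults as in
#'   [enl()] / [epi()]).
#' @return An object of class `"bwoa_denoise"` with elements `fit` (the
#'   underlying `"bwoa_fit"`), `params` (decoded [filter_chain_params()]),
#'   `denoised`, `metrics` (a `"metrics_report"`), `noisy`, `reference`,
#'   `config`, `bounds`, `seed` and `call`.
#' @export
#' @examples
#' ref <- make_phantom("piecewise_constant", size = 64, seed = 1)
#' noisy <- add_noise(ref, noise_spec("salt_pepper", seed = 2))
#' fit <- bwoa_denoise(noisy, ref,
#'                     config = bwoa_config(max_iterations = 3), seed = 1)
#' coef(fit)
#' fit$metrics$psnr
bwoa_denoise <- function(noisy, reference, config = bwoa_config(),
                         bounds = default_bounds(), seed = NULL,
                         enl_rois = default_enl_rois(dim(reference)),
                         epi_rois = default_epi_rois(dim(reference))) {
  assert_image(noisy)
  assert_image(reference)
  assert_same_dim(noisy, reference)
  objective <- function(x)
    denoise_fitness(x, reference, noisy, config$lambda_weight, bounds,
                    config$use_sharpen)
  fit <- bwoa_optimize(objective, bounds, config, seed)
  params <- decode_params(fit$par, bounds)
  denoised <- apply_chain(noisy, params, use_sharpen = config$use_sharpen)
  metrics <- evaluate_all(reference, noisy, denoised, enl_rois, epi_rois)
  structure(list(fit = fit, params = params, denoised = denoised,
                 metrics = metrics, noisy = noisy, reference = reference,
                 config = config, bounds = bounds,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 call = match.call()),
            class = "bwoa_denoise")
}

#' @export
print.bwoa_denoise <- function(x, ...) {
  cat("Black Widow denoising fit\n")
  cat(sprintf("  image          : %d x %d\n", nrow(x$noisy), ncol(x$noisy)))
  cat(sprintf("  evaluations    : %d\n", x$fit$n_evals))
  cat(sprintf("  best fitness   : %.6g\n", x$fit$value))
  cat(sprintf("  PSNR noisy     : %.3f dB\n", psnr(x$reference, x$noisy)))
  cat(sprintf("  PSNR denoised  : %.3f dB\n", x$metrics$psnr))
  invisible(x)
}

#' @export
summary.bwoa_denoise <- function(object, ...) {
  out <- list(
    params = object$params,
    metrics = object$metrics,
    psnr_noisy = psnr(object$reference, object$noisy),
    ssim_noisy = ssim(object$reference, object$noisy),
    best_fitness = object$fit$value,
    n_evals = object$fit$n_evals,
    seed = object$seed
  )
  class(out) <- "summary.bwoa_denoise"
  out
}

#' @export
print.summary.bwoa_denoise <- function(x, ...) {
  print(x$params)
  cat("\n")
  print(x$metrics)
  cat(sprintf("  (noisy input: PSNR %.3f dB, SSIM %.4f)\n",
              x$psnr_noisy, x$ssim_noisy))
  cat(sprintf("  best fitness %.6g after %d evaluations\n",
              x$best_fitness, x$n_evals))
  invisible(x)
}

#' @export
coef.bwoa_denoise <- function(object, ...) {
  unlist(unclass(object$params))
}

#' @export
fitted.bwoa_denoise <- function(object, ...) object$denoised

#' @export
residuals.bwoa_denoise <- function(object, ...) {
  object$reference - object$denoised
}

#' @param newdata A new image to denoise with the fitted chain (defaults to
#'   the image the chain was fitted on).
#' @rdname bwoa_denoise
#' @export
predict.bwoa_denoise <- function(object, newdata = NULL, ...) {
  img <- if (is.null(newdata)) object$noisy else newdata
  apply_chain(img, object$params, use_sharpen = object$config$use_sharpen)
}

#' @export
plot.bwoa_denoise <- function(x, ...) {
  plot(x$fit, main = "BWOA denoising convergence", ...)
}
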