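# Black Widow Optimization Algorithm with Tent-chaotic initialization and a
# Gaussian-plus-Tent perturbation of each candidate.

#' Optimizer configuration
#'
#' All algorithm constants of the Black Widow optimizer. Defaults follow the
#' standard setting for this method: population size 20, 50 iterations,
#' movement speed `m` drawn from \[0.4, 0.9\] and direction `beta` from
#' \[-1, 1\] per individual per iteration, pheromone replacement threshold
#' 0.3.
#'
#' `movement_sign` selects the movement step's direction convention.
#' `"attractive"` (the default) moves an individual toward the current best,
#' `x_i + m (x* - x_i)`; `"as_printed"` uses the sign convention
#' `x_i - m (x* - x_i)`, which repels individuals from the best and is kept
#' available for comparison. See the methods vignette for the rationale.
#'
#' @param population_size Number of individuals N (>= 4; replacement draws
#'   three distinct partners).
#' @param max_iterations Iteration budget T (>= 1).
#' @param m_range,beta_range Ranges of the movement draws.
#' @param pheromone_threshold Replacement threshold in (0, 1).
#' @param lambda_weight Weight of the structural term in the denoising
#'   fitness, in \[0, 1\].
#' @param perturbation_scale Gaussian perturbation standard deviation as a
#'   fraction of each dimension's span.
#' @param use_tent Initialize the population from the Tent map (`FALSE`
#'   falls back to uniform draws; used by the ablation variants).
#' @param use_sharpen Apply the sharpening stage of the filter chain.
#' @param movement_sign `"attractive"` or `"as_printed"`.
#' @param chaos A [chaos_config()].
#' @return An object of class `"bwoa_config"`.
#' @export
bwoa_config <- function(population_size = 20L, max_iterations = 50L,
                        m_range = c(0.4, 0.9), beta_range = c(-1, 1),
                        pheromone_threshold = 0.3, lambda_weight = 0.5,
                        perturbation_scale = 0.1, use_tent = TRUE,
                        use_sharpen = TRUE,
                        movement_sign = c("attractive", "as_printed"),
                        chaos = chaos_config()) {
  movement_sign <- match.arg(movement_sign)
  if (population_size < 4) stop("`population_size` must be >= 4", call. = FALSE)
  if (max_iterations < 1) stop("`max_iterations` must be >= 1", call. = FALSE)
  if (pheromone_threshold <= 0 || pheromone_threshold >= 1)
    stop("`pheromone_threshold` must be in (0, 1)", call. = FALSE)
  if (lambda_weight < 0 || lambda_weight > 1)
    stop("`lambda_weight` must be in [0, 1]", call. = FALSE)
  if (perturbation_scale <= 0) stop("`perturbation_scale` must be > 0", call. = FALSE)
  structure(list(
    population_size = as.integer(population_size),
    max_iterations = as.integer(max_iterations),
    m_range = m_range, beta_range = beta_range,
    pheromone_threshold = pheromone_threshold,
    lambda_weight = lambda_weight,
    perturbation_scale = perturbation_scale,
    use_tent = isTRUE(use_tent), use_sharpen = isTRUE(use_sharpen),
    movement_sign = movement_sign, chaos = chaos
  ), class = "bwoa_config")
}

#' Default search-space bounds for the filter chain
#'
#' Eight continuous dimensions in fixed order: Gaussian sigma in
#' \[0.3, 3\] pixels; the three window-size coordinates in \[0, 1\] (decoded
#' to edges 3/5/7 by [decode_params()]); bilateral range sigma in \[5, 75\]
#' intensity units; bilateral spatial sigma in \[0.5, 5\] pixels; bilateral
#' window coordinate in \[0, 1\]; sharpening amount in \[0, 2\].
#'
#' @return A [bwoa_bounds()] with named dimensions.
#' @export
default_bounds <- function() {
  nm <- c("gaussian_sigma", "gaussian_ksize", "median_ksize", "mean_ksize",
          "bilateral_sigma_r", "bilateral_sigma_d", "bilateral_ksize",
          "sharpen_amount")
  bwoa_bounds(
    lower = stats::setNames(c(0.3, 0, 0, 0, 5, 0.5, 0, 0), nm),
    upper = stats::setNames(c(3, 1, 1, 1, 75, 5, 1, 2), nm)
  )
}

decode_ksize <- function(x, lo, hi) {
  u <- (x - lo) / (hi - lo)
  c(3L, 5L, 7L)[pmin.int(3L, floor(u * 3) + 1L)]
}

#' Decode a search point into filter-chain parameters
#'
#' Continuous sigma and amount coordinates pass through; the window-size
#' coordinates are partitioned into three equal bins mapped to edges
#' {3, 5, 7}. Decoding is deterministic, so it is idempotent on a fixed
#' point.
#'
#' @param x Numeric vector of length 8 within `bounds` (order as in
#'   [default_bounds()]).
#' @param bounds A [bwoa_bounds()] of dimension 8.
#' @return A [filter_chain_params()].
#' @export
decode_params <- function(x, bounds = default_bounds()) {
  stopifnot(inherits(bounds, "bwoa_bounds"))
  if (length(x) != 8L || length(bounds$lower) != 8L)
    stop("the filter-chain search space has 8 dimensions", call. = FALSE)
  x <- unname(x)
  if (any(x < bounds$lower - 1e-9) || any(x > bounds$upper + 1e-9))
    stop("`x` lies outside the search bounds", call. = FALSE)
  lo <- bounds$lower; hi <- bounds$upper
  filter_chain_params(
    gaussian_sigma   = x[1],
    gaussian_ksize   = decode_ksize(x[2], lo[2], hi[2]),
    median_ksize     = decode_ksize(x[3], lo[3], hi[3]),
    mean_ksize       = decode_ksize(x[4], lo[4], hi[4]),
    bilateral_sigma_r = x[5],
    bilateral_sigma_d = x[6],
    bilateral_ksize  = decode_ksize(x[7], lo[7], hi[7]),
    sharpen_amount   = x[8]
  )
}

#' Denoising fitness of a search point
#'
#' Applies the decoded filter chain to the noisy image and scores the result
#' against the clean reference:
#' `lambda * (1 - SSIM) + (1 - lambda) * MSE / L^2` with `L = 255`. The score
#' is non-negative and zero only for perfect reconstruction; the optimizer
#' minimizes it, trading structural similarity against normalized squared
#' error.
#'
#' @param x Search point (length 8, within `bounds`).
#' @param reference Clean reference image.
#' @param noisy Noisy image of identical dimensions.
#' @param lambda Weight of the structural term, in \[0, 1\].
#' @param bounds A [bwoa_bounds()].
#' @param use_sharpen Apply the sharpening stage.
#' @return Non-negative scalar fitness (smaller is better).
#' @export
denoise_fitness <- function(x, reference, noisy, lambda = 0.5,
                            bounds = default_bounds(), use_sharpen = TRUE) {
  assert_same_dim(reference, noisy)
  den <- apply_chain(noisy, decode_params(x, bounds), use_sharpen = use_sharpen)
  lambda * (1 - ssim(reference, den)) + (1 - lambda) * mse(reference, den) / 255^2
}

#' Movement step
#'
#' Updates a position relative to the current best using the two-branch rule:
#' with step `delta = x_best - x_i`, `beta >= 0` gives `x_i + s * m * delta`
#' and `beta < 0` gives `x_i + s * m * delta + beta * delta`, where `s` is +1
#' in `"attractive"` mode and -1 in `"as_printed"` mode. The caller clips the
#' result to the bounds.
#'
#' @param x_i Current position.
#' @param x_best Current best position.
#' @param m Speed draw in \[0.4, 0.9\].
#' @param beta Direction draw in \[-1, 1\].
#' @param sign `"attractive"` or `"as_printed"`.
#' @return Updated (unclipped) position.
#' @export
move_widow <- function(x_i, x_best, m, beta,
                       sign = c("attractive", "as_printed")) {
  sign <- match.arg(sign)
  if (m < 0.4 || m > 0.9) stop("`m` must be in [0.4, 0.9]", call. = FALSE)
  if (beta < -1 || beta > 1) stop("`beta` must be in [-1, 1]", call. = FALSE)
  delta <- x_best - x_i
  s <- if (sign == "attractive") 1 else -1
  out <- x_i + s * m * delta
  if (beta < 0) out <- out + beta * delta
  out
}

clip_to_bounds <- function(x, bounds) {
  pmin(pmax(x, bounds$lower), bounds$upper)
}

#' Gaussian perturbation followed by Tent remapping
#'
#' Adds per-dimension Gaussian noise with standard deviation
#' `scale * (upper - lower)` to a position, normalizes each coordinate to
#' \[0, 1\], clips, applies one Tent-map step, and rescales into the bounds.
#' The Tent step makes the perturbation exploratory: iterated through the
#' chaotic map, candidate coordinates wander densely over the search
#' interval instead of staying local.
#'
#' @param x Position to perturb.
#' @param bounds A [bwoa_bounds()].
#' @param scale Noise scale as a fraction of each dimension's span.
#' @param mu Tent control parameter.
#' @return Perturbed position, guaranteed within bounds.
#' @export
gaussian_tent_perturb <- function(x, bounds, scale = 0.1, mu = 2) {
  stopifnot(inherits(bounds, "bwoa_bounds"))
  if (scale <= 0) stop("`scale` must be > 0", call. = FALSE)
  span <- bounds$upper - bounds$lower
  y <- x + rnorm(length(x), 0, scale * span)
  u <- pmin(pmax((y - bounds$lower) / span, 0), 1)
  bounds$lower + span * tent_step(u, mu)
}

#' Pheromone update
#'
#' Raises the pheromone by `f_old / f_sum` when the individual improved
#' (its new fitness is no worse under minimization), lowers it by the same
#' amount otherwise; the result is clipped to \[0, 1\].
#'
#' @param phi Current pheromone in \[0, 1\].
#' @param f_old,f_new Previous and new fitness of the individual.
#' @param f_sum Sum of the population's fitness values (> 0).
#' @return Updated pheromone in \[0, 1\].
#' @export
update_pheromone <- function(phi, f_old, f_new, f_sum) {
  if (!is.finite(f_sum) || f_sum <= 0)
    stop("`f_sum` must be > 0 (degenerate population)", call. = FALSE)
  step <- f_old / f_sum
  out <- if (f_old >= f_new) phi + step else phi - step
  min(max(out, 0), 1)
}

#' Replacement of a weak individual
#'
#' When the pheromone of individual `i` is at or below the threshold, its
#' position is rebuilt from three distinct random partners as
#' `x_r1 + sigma * (x_r2 - x_r3)` with `sigma ~ Bernoulli(1/2)`, clipped to
#' the bounds; otherwise the position is kept. The caller resets the
#' pheromone to 1 and re-evaluates the fitness on replacement.
#'
#' @param i Index of the individual.
#' @param positions N x d population matrix.
#' @param pheromone Pheromone vector.
#' @param bounds A [bwoa_bounds()].
#' @param phi_th Replacement threshold.
#' @return List with elements `position` and `replaced` (logical).
#' @export
replace_if_weak <- function(i, positions, pheromone, bounds, phi_th = 0.3) {
  n <- nrow(positions)
  if (n < 4) stop("replacement needs a population of at least 4", call. = FALSE)
  if (pheromone[i] > phi_th)
    return(list(position = positions[i, ], replaced = FALSE))
  partners <- sample(setdiff(seq_len(n), i), 3L)
  sigma <- sample(0:1, 1L)
  pos <- positions[partners[1], ] + sigma * (positions[partners[2], ] - positions[partners[3], ])
  list(position = clip_to_bounds(pos, bounds), replaced = TRUE)
}

#' Run the Black Widow optimizer
#'
#' Minimizes `objective` over a box-bounded continuous space. The population
#' is initialized from a Tent chaotic sequence (or uniformly when
#' `config$use_tent` is `FALSE`); each iteration every individual proposes a
#' movement step relative to the current best plus a Gaussian-plus-Tent
#' perturbation of its own retained position, adopts the better proposal
#' when it does not worsen its fitness (greedy retention), pheromones score
#' the attempt via relative fitness, and weak individuals are replaced. The
#' best-so-far solution is retained greedily, so the recorded best-fitness
#' history is non-increasing.
#'
#' @param objective Function mapping a position vector to a finite scalar
#'   (minimized).
#' @param bounds A [bwoa_bounds()].
#' @param config A [bwoa_config()].
#' @param seed Integer seed for reproducibility, or `NULL` to use the
#'   current RNG state.
#' @return An object of class `"bwoa_fit"`: a list with `par` (best
#'   position), `value` (best fitness), `history` (data frame with
#'   `iteration`, `best_fitness`, `mean_pheromone`), `population`,
#'   `fitness`, `pheromone`, `n_evals`, `x0` (Tent seed used, `NA` for
#'   uniform initialization), `config`, `bounds` and `seed`.
#' @export
#' @examples
#' b <- bwoa_bounds(c(-5, -5), c(5, 5))
#' fit <- bwoa_optimize(function(x) sum((x - c(1, -2))^2), b,
#'                      bwoa_config(max_iterations = 25), seed = 1)
#' fit$par
bwoa_optimize <- function(objective, bounds, config = bwoa_config(), seed = NULL) {
  stopifnot(inherits(bounds, "bwoa_bounds"), inherits(config, "bwoa_config"))
  with_seed(seed, {
    n <- config$population_size
    d <- length(bounds$lower)
    span <- bounds$upper - bounds$lower

    if (config$use_tent) {
      pos <- init_positions(bounds, n, d, config$chaos)
      x0 <- attr(attr(pos, "chaos"), "x0")
    } else {
      pos <- matrix(runif(n * d), n, d, byrow = TRUE)
      pos <- sweep(sweep(pos, 2, span, "*"), 2, bounds$lower, "+")
      x0 <- NA_real_
    }
    pos <- unclass(pos)
    attr(pos, "chaos") <- NULL

    eval_fit <- function(x) {
      f <- objective(x)
      if (!is.finite(f))
        stop("objective returned a non-finite value at [",
             paste(signif(x, 4), collapse = ", "), "]", call. = FALSE)
      f
    }
    fit <- apply(pos, 1, eval_fit)
    n_evals <- n
    pher <- rep(1, n)

    best_i <- which.min(fit)  # ties: lowest index
    best_pos <- pos[best_i, ]
    best_fit <- fit[best_i]

    hist_best <- numeric(config$max_iterations)
    hist_pher <- numeric(config$max_iterations)

    for (t in seq_len(config$max_iterations)) {
      f_sum <- sum(fit)
      for (i in seq_len(n)) {
        m <- runif(1, config$m_range[1], config$m_range[2])
        beta <- runif(1, config$beta_range[1], config$beta_range[2])
        cand <- clip_to_bounds(
          move_widow(pos[i, ], best_pos, m, beta, config$movement_sign), bounds)
        f_cand <- eval_fit(cand)
        # supplementary exploration: Gaussian noise around the individual's
        # retained (never-worsened) position, remapped through the Tent map
        pert <- gaussian_tent_perturb(pos[i, ], bounds, config$perturbation_scale,
                                      config$chaos$mu)
        f_pert <- eval_fit(pert)
        n_evals <- n_evals + 2L
        if (f_pert < f_cand) {
          cand <- pert
          f_cand <- f_pert
        }
        # pheromone scores the attempt; the position updates greedily
        pher[i] <- update_pheromone(pher[i], fit[i], f_cand, f_sum)
        if (f_cand <= fit[i]) {
          pos[i, ] <- cand
          fit[i] <- f_cand
        }
        if (fit[i] < best_fit) {
          best_fit <- fit[i]
          best_pos <- pos[i, ]
        }
      }
      for (i in seq_len(n)) {
        rep_i <- replace_if_weak(i, pos, pher, bounds, config$pheromone_threshold)
        if (rep_i$replaced) {
          pos[i, ] <- rep_i$position
          fit[i] <- eval_fit(rep_i$position)
          n_evals <- n_evals + 1L
          pher[i] <- 1
          if (fit[i] < best_fit) {
            best_fit <- fit[i]
            best_pos <- pos[i, ]
          }
        }
      }
      hist_best[t] <- best_fit
      hist_pher[t] <- mean(pher)
    }

    structure(list(
      par = stats::setNames(best_pos, bounds$names),
      value = best_fit,
      history = data.frame(iteration = seq_len(config$max_iterations),
                           best_fitness = hist_best,
                           mean_pheromone = hist_pher),
      population = pos, fitness = fit, pheromone = pher,
      n_evals = n_evals, x0 = x0, config = config, bounds = bounds,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    ), class = "bwoa_fit")
  })
}

#' @export
print.bwoa_fit <- function(x, ...) {
  cat("Black Widow optimizer fit\n")
  cat(sprintf("  dimensions     : %d\n", length(x$par)))
  cat(sprintf("  population / T : %d / %d\n",
              x$config$population_size, x$config$max_iterations))
  cat(sprintf("  evaluations    : %d\n", x$n_evals))
  cat(sprintf("  best fitness   : %.6g\n", x$value))
  cat("  best position  :", paste(signif(x$par, 5), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn bwoa_optimize Convergence plot: best-so-far fitness per
#'   iteration (log scale when positive) with the mean pheromone overlaid.
#' @param x A `"bwoa_fit"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bwoa_fit <- function(x, ...) {
  h <- x$history
  logy <- all(h$best_fitness > 0)
  graphics::plot(h$iteration, h$best_fitness, type = "s",
                 log = if (logy) "y" else "",
                 xlab = "iteration", ylab = "best fitness", ...)
  graphics::par(new = TRUE)
  graphics::plot(h$iteration, h$mean_pheromone, type = "l", lty = 2,
                 col = "grey50", axes = FALSE, xlab = "", ylab = "",
                 ylim = c(0, 1))
  graphics::axis(4, col.axis = "grey50")
  graphics::mtext("mean pheromone", side = 4, line = 2, col = "grey50", cex = 0.8)
  invisible(x)
}
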