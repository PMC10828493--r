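test_that("decode_params bins window coordinates and passes sigmas through", {
  b <- default_bounds()
  # bin centers of the [0,1] window coordinates map to 3, 5, 7
  centers <- c(1 / 6, 1 / 2, 5 / 6)
  for (i in 1:3) {
    x <- c(1.2, centers[i], centers[i], centers[i], 30, 2, centers[i], 0.5)
    p <- decode_params(x, b)
    k <- c(3L, 5L, 7L)[i]
    expect_identical(c(p$gaussian_ksize, p$median_ksize, p$mean_ksize,
                       p$bilateral_ksize), rep(k, 4))
    expect_equal(p$gaussian_sigma, 1.2)
    expect_equal(p$bilateral_sigma_r, 30)
    expect_equal(p$sharpen_amount, 0.5)
  }
  # lower bound decodes to the minimal legal chain
  pmin_ <- decode_params(b$lower, b)
  expect_identical(c(pmin_$gaussian_ksize, pmin_$median_ksize,
                     pmin_$mean_ksize, pmin_$bilateral_ksize), rep(3L, 4))
  # decoding is deterministic
  x <- c(2, 0.9, 0.2, 0.5, 60, 4, 0.4, 1.5)
  expect_identical(decode_params(x, b), decode_params(x, b))
  expect_error(decode_params(c(10, 0, 0, 0, 30, 2, 0, 0.5), b), "bounds")
})

test_that("denoise_fitness is zero for perfect reconstruction and obeys the weights", {
  ref <- matrix(128, 16, 16)  # constant: every chain stage is a fixed point
  b <- default_bounds()
  x <- c(1, 0.5, 0.5, 0.5, 30, 2, 0.5, 1)
  expect_equal(denoise_fitness(x, ref, ref, lambda = 0.5, b), 0, tolerance = 1e-12)

  # lambda = 0 with MSE = L^2: all-zero reference vs all-255 input
  zero <- matrix(0, 16, 16); full <- matrix(255, 16, 16)
  expect_equal(denoise_fitness(x, zero, full, lambda = 0, b), 1, tolerance = 1e-12)

  # lambda = 1 reduces to 1 - SSIM
  nz <- add_noise(make_phantom("piecewise_constant", 32, 1),
                  noise_spec("gaussian", seed = 3))
  rf <- make_phantom("piecewise_constant", 32, 1)
  den <- apply_chain(nz, decode_params(x, b))
  expect_equal(denoise_fitness(x, rf, nz, lambda = 1, b), 1 - ssim(rf, den),
               tolerance = 1e-12)
})

test_that("move_widow implements both branch and sign conventions", {
  expect_equal(move_widow(2, 5, 0.5, 0.2, "as_printed"), 0.5)
  expect_equal(move_widow(2, 5, 0.5, -0.5, "as_printed"), -1)
  expect_equal(move_widow(2, 5, 0.5, 0.2, "attractive"), 3.5)
  expect_equal(move_widow(2, 5, 0.5, -0.5, "attractive"), 2)
  for (sgn in c("as_printed", "attractive"))
    expect_equal(move_widow(c(1, 2), c(1, 2), 0.7, -0.3, sgn), c(1, 2))
  expect_error(move_widow(0, 1, 0.2, 0), "m")
  expect_error(move_widow(0, 1, 0.5, 1.5), "beta")
})

test_that("gaussian_tent_perturb composes noise with one tent step inside bounds", {
  b <- bwoa_bounds(c(0, -10), c(10, 10))
  # negligible noise: deterministic tent transform of the point itself
  set.seed(1)
  out <- gaussian_tent_perturb(c(3, -2), b, scale = 1e-15)
  expect_equal(out, c(0 + 10 * tent_step(0.3), -10 + 20 * tent_step(0.4)),
               tolerance = 1e-6)

  set.seed(2)
  draws <- t(replicate(1000, gaussian_tent_perturb(c(5, 0), b, scale = 0.1)))
  expect_true(all(draws[, 1] >= 0 & draws[, 1] <= 10))
  expect_true(all(draws[, 2] >= -10 & draws[, 2] <= 10))
  expect_gt(sd(draws[, 1]), 0)
  expect_gt(sd(draws[, 2]), 0)
})

test_that("update_pheromone follows the relative-fitness rule with clipping", {
  expect_equal(update_pheromone(0.5, 1, 0.5, 4), 0.75)
  expect_equal(update_pheromone(0.5, 1, 2, 4), 0.25)
  expect_equal(update_pheromone(0.95, 1, 0.5, 4), 1)    # clipped above
  expect_equal(update_pheromone(0.1, 2, 3, 4), 0)       # clipped below
  expect_equal(update_pheromone(0.5, 1, 1, 4), 0.75)    # equality counts as improvement
  expect_error(update_pheromone(0.5, 1, 1, 0), "f_sum")
})

test_that("replace_if_weak keeps strong individuals and rebuilds weak ones", {
  b <- bwoa_bounds(rep(-10, 1), rep(10, 1))
  pos <- matrix(c(2, 5, 3, -4, 7), ncol = 1)
  pher <- c(0.8, 0.1, 0.5, 0.5, 0.5)

  kept <- replace_if_weak(1, pos, pher, b, 0.3)
  expect_false(kept$replaced)
  expect_equal(kept$position, pos[1, ])

  # every replacement is x_r1 or x_r1 + (x_r2 - x_r3) over distinct others
  others <- pos[-2, 1]
  valid <- c(others, apply(expand.grid(others, others, others), 1,
                           function(v) v[1] + v[2] - v[3]))
  valid <- pmin(pmax(valid, -10), 10)
  set.seed(4)
  for (rep_i in 1:50) {
    r <- replace_if_weak(2, pos, pher, b, 0.3)
    expect_true(r$replaced)
    expect_true(any(abs(valid - r$position) < 1e-12))
    expect_true(r$position >= -10 && r$position <= 10)
  }
  expect_error(replace_if_weak(1, pos[1:3, , drop = FALSE], pher[1:3], b, 0.3),
               "at least 4")
})

test_that("bwoa_optimize honors the iteration contract and is deterministic", {
  b <- bwoa_bounds(c(-5, -5), c(5, 5))
  f <- function(x) sum((x - c(1, -2))^2)

  one <- bwoa_optimize(f, b, bwoa_config(max_iterations = 1), seed = 3)
  expect_equal(nrow(one$history), 1)

  f1 <- bwoa_optimize(f, b, bwoa_config(max_iterations = 10), seed = 5)
  f2 <- bwoa_optimize(f, b, bwoa_config(max_iterations = 10), seed = 5)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$par, f2$par)

  expect_error(bwoa_optimize(function(x) NaN, b, bwoa_config(max_iterations = 1),
                             seed = 1), "non-finite")
})

test_that("bwoa_optimize keeps positions in bounds and pheromones in [0,1]", {
  b <- bwoa_bounds(c(0, 100), c(1, 200))
  f <- function(x) abs(x[1] - 0.3) + abs(x[2] - 150) / 100
  fit <- bwoa_optimize(f, b, bwoa_config(max_iterations = 20), seed = 8)
  expect_true(all(fit$population[, 1] >= 0 & fit$population[, 1] <= 1))
  expect_true(all(fit$population[, 2] >= 100 & fit$population[, 2] <= 200))
  expect_true(all(fit$pheromone >= 0 & fit$pheromone <= 1))
  expect_true(all(fit$par >= b$lower & fit$par <= b$upper))
  expect_true(all(diff(fit$history$best_fitness) <= 0))
})

test_that("tent and uniform initializations differ but share the optimizer API", {
  b <- bwoa_bounds(c(-5, -5), c(5, 5))
  f <- function(x) sum(x^2)
  cfg_on <- bwoa_config(max_iterations = 1, use_tent = TRUE)
  cfg_off <- bwoa_config(max_iterations = 1, use_tent = FALSE)
  on <- bwoa_optimize(f, b, cfg_on, seed = 9)
  off <- bwoa_optimize(f, b, cfg_off, seed = 9)
  expect_false(isTRUE(all.equal(on$population, off$population)))
  expect_true(all(on$population >= -5 & on$population <= 5))
  expect_true(all(off$population >= -5 & off$population <= 5))
  expect_true(is.finite(on$x0))
  expect_true(is.na(off$x0))
})
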