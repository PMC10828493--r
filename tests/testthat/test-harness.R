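test_that("phantoms are deterministic, in range, and structured as documented", {
  a <- make_phantom("piecewise_constant", 64, seed = 1)
  b <- make_phantom("piecewise_constant", 64, seed = 1)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 255))
  expect_false(identical(a, make_phantom("piecewise_constant", 64, seed = 2)))

  g <- make_phantom("gradient", 64)
  expect_true(all(apply(g, 1, function(r) all(diff(r) > 0))))

  e <- make_phantom("edges", 64)
  expect_setequal(unique(as.numeric(e)), c(40, 215))

  bl <- make_phantom("blobs", 128, seed = 7)
  # upper-left background patch is homogeneous: ENL saturates
  bg <- enl(bl, list(roi(0, 0, 32, 32)))
  expect_true(all(attr(bg, "saturated")))

  expect_error(make_phantom("blobs", 16), ">= 32")
})

test_that("noise models preserve dimensions, range, and seed determinism", {
  img <- make_phantom("piecewise_constant", 64, seed = 1)
  for (kind in c("gaussian", "salt_pepper", "poisson", "speckle")) {
    sp <- noise_spec(kind, seed = 3)
    n1 <- add_noise(img, sp)
    n2 <- add_noise(img, sp)
    expect_identical(n1, n2)
    expect_equal(dim(n1), dim(img))
    expect_true(all(n1 >= 0 & n1 <= 255))
    expect_false(identical(n1, img))
  }
})

test_that("salt-and-pepper hit fraction matches the binomial expectation", {
  img <- matrix(128, 100, 100)
  noisy <- add_noise(img, noise_spec("salt_pepper", sp_density = 0.1, seed = 3))
  frac <- mean(noisy %in% c(0, 255))
  ci <- 2.58 * sqrt(0.1 * 0.9 / 1e4)  # 99% binomial interval
  expect_true(frac > 0.1 - ci && frac < 0.1 + ci)
})

test_that("gaussian noise has the configured standard deviation", {
  img <- matrix(128, 100, 100)
  noisy <- add_noise(img, noise_spec("gaussian", gaussian_sigma = 25, seed = 7))
  emp_sd <- sd(noisy[21:80, 21:80] - 128)
  expect_lt(abs(emp_sd - 25) / 25, 0.1)
})

test_that("degenerate noise inputs behave as their models dictate", {
  zero <- matrix(0, 32, 32)
  expect_identical(add_noise(zero, noise_spec("poisson", seed = 1)), zero)
  expect_identical(add_noise(zero, noise_spec("speckle", seed = 1)), zero)
  expect_error(noise_spec("gaussian", sp_density = 1.5), "sp_density")
  expect_error(noise_spec("nonsense"), "arg")
})

test_that("png round trip quantizes by round-half-away-from-zero", {
  img <- matrix(c(0, 0.4, 0.6, 1.5, 127.5, 254.5, 255, 200, 100.2), 3, 3)
  path <- withr::local_tempfile(fileext = ".png")
  write_image(img, path)
  back <- read_image(path)
  expect_equal(back, floor(img + 0.5), tolerance = 1e-9)
  expect_error(read_image("does/not/exist.png"), "cannot read")
})

test_that("run_denoise writes reproducible reports and improves the image", {
  dir <- withr::local_tempdir()
  ref <- make_phantom("piecewise_constant", 64, seed = 1)
  noisy <- add_noise(ref, noise_spec("salt_pepper", seed = 11))
  ref_p <- file.path(dir, "ref.png"); noisy_p <- file.path(dir, "noisy.png")
  write_image(ref, ref_p); write_image(noisy, noisy_p)

  cfg_p <- file.path(dir, "cfg.yaml")
  writeLines("bwoa:\n  max_iterations: 2\n  population_size: 6", cfg_p)

  out <- lapply(1:2, function(k) {
    paths <- list(img = file.path(dir, paste0("den", k, ".png")),
                  rep = file.path(dir, paste0("rep", k, ".json")),
                  his = file.path(dir, paste0("his", k, ".csv")),
                  man = file.path(dir, paste0("man", k, ".json")))
    fit <- run_denoise(noisy_p, ref_p, cfg_p, out_image = paths$img,
                       report_path = paths$rep, history_path = paths$his,
                       manifest_path = paths$man, seed = 11)
    c(paths, fit = list(fit))
  })
  # byte-identical outputs under the same seed
  expect_identical(readBin(out[[1]]$rep, "raw", 1e6), readBin(out[[2]]$rep, "raw", 1e6))
  expect_identical(readBin(out[[1]]$his, "raw", 1e6), readBin(out[[2]]$his, "raw", 1e6))
  expect_identical(readBin(out[[1]]$man, "raw", 1e6), readBin(out[[2]]$man, "raw", 1e6))
  expect_identical(readBin(out[[1]]$img, "raw", 1e6), readBin(out[[2]]$img, "raw", 1e6))

  rep1 <- jsonlite::read_json(out[[1]]$rep)
  expect_named(rep1, c("mse", "psnr", "ssim", "enl", "epi"))
  # the quantized reference read back differs from ref only by rounding
  expect_gt(rep1$psnr, psnr(ref, noisy) - 0.1)

  his <- read.csv(out[[1]]$his)
  expect_named(his, c("iteration", "best_fitness", "mean_pheromone"))
  expect_equal(nrow(his), 2)

  man <- jsonlite::read_json(out[[1]]$man)
  expect_equal(man$seed, 11)
  expect_true(man$use_tent)
})

test_that("run_denoise on a clean input reaches near-zero fitness", {
  dir <- withr::local_tempdir()
  ref <- make_phantom("piecewise_constant", 64, seed = 2)
  p <- file.path(dir, "ref.png")
  write_image(ref, p)
  cfg_p <- file.path(dir, "cfg.yaml")
  writeLines("bwoa:\n  max_iterations: 2\n  population_size: 6", cfg_p)
  fit <- run_denoise(p, p, cfg_p, seed = 1)
  # constant-dominated phantom: the chain can nearly reproduce the input
  expect_lt(fit$fit$value, 0.05)
  expect_gt(fit$metrics$ssim, 0.9)
})

test_that("run_ablation pairs variants on identical noisy inputs", {
  ref <- make_phantom("piecewise_constant", 48, seed = 1)
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "ablation.csv")
  cfg_p <- file.path(dir, "cfg.yaml")
  writeLines("bwoa:\n  max_iterations: 2\n  population_size: 6", cfg_p)
  tab <- run_ablation(ref, noise_spec("speckle"), cfg_p, seeds = c(1, 2),
                      csv_path = csv)
  expect_equal(nrow(tab), 6)
  expect_setequal(unique(tab$variant), c("BWOA", "BWOA1.0", "BWOA2.0"))
  expect_true(all(c("mse", "psnr", "ssim", "enl", "epi") %in% names(tab)))
  # paired design: identical noisy input within each seed
  for (s in c(1, 2))
    expect_equal(length(unique(tab$psnr_noisy[tab$seed == s])), 1L)
  # variant flags wired through
  expect_false(any(tab$use_sharpen[tab$variant == "BWOA2.0"]))
  expect_false(any(tab$use_tent[tab$variant == "BWOA1.0"]))
  expect_true(file.exists(csv))
  expect_identical(names(read.csv(csv)), names(tab))
})
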