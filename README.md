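# chaoswidow

Denoising of 8-bit grayscale medical-style images by **metaheuristic filter
tuning**: a Black Widow Optimization Algorithm (BWOA), seeded from a Tent
chaotic map, searches the parameter space of a fixed five-stage filter chain
(Gaussian → median → mean → bilateral → sharpening) for the setting that
best restores a noisy image toward a clean reference.

The package is for researchers benchmarking denoising pipelines on images
corrupted by the four standard noise mechanisms — additive Gaussian,
salt-and-pepper, Poisson, and multiplicative speckle — and for anyone who
wants a reproducible, seed-deterministic implementation of the
chaos-initialized BWOA itself as a general box-bounded optimizer.

## The method in brief

Each of N = 20 "black widows" encodes a chain setting
x = (σ_g, k_g, k_med, k_mean, σ_r, σ_d, k_bil, a) ∈ ℝ⁸ (window sizes are
decoded from continuous coordinates to {3, 5, 7}). The optimizer minimizes

    f(x) = λ (1 − SSIM(R, D_x)) + (1 − λ) MSE(R, D_x) / 255²,   λ = 0.5,

where D_x is the chain output on the noisy image and R the clean reference.
The population is initialized from the Tent map
x_{i+1} = 2x_i (x_i ≤ ½), 2(1 − x_i) otherwise; each iteration combines an
attraction step toward the current best with random speed m ∈ [0.4, 0.9]
and direction β ∈ [−1, 1], a Gaussian-plus-Tent chaotic perturbation, a
pheromone score φ_i ∈ [0, 1] tracking relative success, and replacement of
individuals with φ_i ≤ 0.3 by x_r1 + σ(x_r2 − x_r3), σ ∈ {0, 1}. Quality is
reported as MSE, PSNR (n = 8 bits), SSIM (k₁ = 0.01, k₂ = 0.03, global
form), ENL averaged over three homogeneous ROIs, and EPI on boundary ROIs.
See the methods vignette (`vignettes/denoising-methodology.Rmd`) for the
full account.

## Worked example

```r
library(chaoswidow)

ref   <- make_phantom("piecewise_constant", size = 128, seed = 1)
noisy <- add_noise(ref, noise_spec("salt_pepper", sp_density = 0.05, seed = 11))
fit   <- bwoa_denoise(noisy, ref, config = bwoa_config(max_iterations = 8), seed = 11)
summary(fit)
```

```
Filter chain parameters (Gaussian -> median -> mean -> bilateral -> sharpen)
  Gaussian:  sigma = 0.418, ksize = 3
  Median:    ksize = 3
  Mean:      ksize = 3
  Bilateral: sigma_r = 44.34, sigma_d = 2.591, ksize = 5
  Sharpen:   amount = 1.200

Image quality metrics
  MSE  : 30.0380
  PSNR : 33.354 dB
  SSIM : 0.9945
  ENL  : 12.95
  EPI  : 5.8359
  (noisy input: PSNR 18.257 dB, SSIM 0.8443)
  best fitness 0.00295669 after 340 evaluations
```

Reading the output: the optimizer chose a light Gaussian pre-smooth
(σ ≈ 0.42), the 3×3 median that kills the impulses, minimal mean smoothing,
a fairly permissive bilateral stage, and a strong sharpening blend to
restore edge contrast. That lifted PSNR from 18.3 dB (noisy) to 33.4 dB —
a 15 dB gain — and SSIM from 0.844 to 0.995. The EPI of 5.8 says the
denoised image has far weaker boundary-ROI gradients than the impulse-ridden
noisy input, as expected (the index is the noisy-over-denoised gradient
ratio). `coef(fit)` returns the decoded parameters, `fitted(fit)` the
denoised image, `predict(fit, img)` applies the fitted chain to another
image, and `plot(fit)` draws the convergence history.

A command-line front end covering phantom generation, noise injection,
denoising, evaluation, and the ablation study (full method vs. no-Tent /
no-sharpening variants) is installed at
`system.file("cli/chaoswidow.R", package = "chaoswidow")`; an example YAML
configuration is at `system.file("extdata/config.yaml", package = "chaoswidow")`.

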