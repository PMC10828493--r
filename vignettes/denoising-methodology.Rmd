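---
title: "Chaos-seeded Black Widow optimization of a denoising filter chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chaos-seeded Black Widow optimization of a denoising filter chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaoswidow)
```

## The problem

Grayscale medical-style images (CT slices are the motivating case) are
degraded by several noise mechanisms at once: additive sensor noise,
impulse ("salt-and-pepper") corruption, photon-counting (Poisson) noise, and
multiplicative speckle. Classical spatial filters each handle one of these
well and the others poorly, so a practical recipe is a *chain* of filters.
The catch is that the chain's quality depends strongly on its parameters —
kernel widths, range/spatial bandwidths, sharpening strength — and the best
setting varies with the image and the noise. `chaoswidow` treats parameter
selection as a continuous optimization problem and solves it with a Black
Widow Optimization Algorithm (BWOA) whose population is seeded from a Tent
chaotic map.

The package has three layers:

* a fixed five-stage filter chain (Gaussian → median → mean → bilateral →
  sharpening) with eight tunable parameters;
* full-reference quality metrics — MSE, PSNR, SSIM, ENL, EPI — with
  rectangular region-of-interest (ROI) support;
* the optimizer itself, wrapped in the fitting function `bwoa_denoise()`.

Tuning requires a clean reference image; blind denoising is out of scope.

## The filter chain

The stages are applied in a fixed order (the order is not searched over):

1. **Gaussian** smoothing with kernel weights proportional to
   $\exp(-(x^2+y^2)/2\sigma^2)$, renormalized over the discrete window.
2. **Median** over a $k \times k$ window — the impulse-noise workhorse.
3. **Mean** over a uniform $k \times k$ window.
4. **Bilateral**: each neighbor weighted by the product of a spatial
   Gaussian (bandwidth $\sigma_d$, pixels) and a range Gaussian on the
   intensity difference (bandwidth $\sigma_r$, intensity units), which
   smooths while preserving edges.
5. **Sharpening**: a blend $(1-a)\,I + a\,(I \ast K)$ with the fixed
   $3\times3$ kernel $K = [[0,-1,0],[-1,5,-1],[0,-1,0]]$ (sums to 1), so
   $a=0$ is the identity and $a=1$ is plain convolution.

Window edges are restricted to $\{3,5,7\}$. All filters use edge-repeating
reflect padding — this avoids the border darkening that zero padding would
cause, which matters because the edge-preservation metric is evaluated on
boundary ROIs. Every stage clips its output to $[0,255]$ on exit, and every
stage is a fixed point on constant images.

Two of the standard filter formulas circulate in garbled printed forms (a
Gaussian kernel with a sign-flipped exponent and a distance-increasing
normalizer; a bilateral weight mixing the two bandwidths). The package
implements the standard textbook forms stated above, which are the only
readings consistent with the filters' described behavior.

## The search space and fitness

The optimizer works on $d=8$ continuous coordinates:

| coordinate | decoded meaning | default bounds |
|---|---|---|
| `gaussian_sigma` | Gaussian stage $\sigma$ (pixels) | $[0.3, 3]$ |
| `gaussian_ksize` | window bin coordinate | $[0,1] \to \{3,5,7\}$ |
| `median_ksize` | window bin coordinate | $[0,1] \to \{3,5,7\}$ |
| `mean_ksize` | window bin coordinate | $[0,1] \to \{3,5,7\}$ |
| `bilateral_sigma_r` | range bandwidth (intensity) | $[5, 75]$ |
| `bilateral_sigma_d` | spatial bandwidth (pixels) | $[0.5, 5]$ |
| `bilateral_ksize` | window bin coordinate | $[0,1] \to \{3,5,7\}$ |
| `sharpen_amount` | blend weight $a$ | $[0, 2]$ |

Window coordinates are decoded by partitioning $[0,1]$ into three equal
bins (`decode_params()`); decoding is deterministic. Keeping the search
space fully continuous lets the optimizer ignore the mixed discrete nature
of the problem.

The fitness (minimized) scalarizes reconstruction quality:

$$f(x) \;=\; \lambda\,\bigl(1 - \mathrm{SSIM}(R, D_x)\bigr) \;+\;
 (1-\lambda)\,\frac{\mathrm{MSE}(R, D_x)}{255^2},$$

where $R$ is the reference, $D_x$ the chain output at parameters $x$, and
$\lambda = 0.5$ by default. The normalized MSE term is a bounded, monotone
surrogate of PSNR: combining the two on the raw dB scale would let the
unbounded PSNR dominate. $f$ is non-negative and zero only for perfect
reconstruction.

## The optimizer

**Tent-chaotic initialization.** The Tent map
$x_{i+1} = \mu x_i$ for $x_i \le 1/2$, $\mu(1-x_i)$ otherwise, with
$\mu = 2$, generates a well-spread, non-repeating sequence on $[0,1]$. One
sequence of length $N \cdot d$ is consumed row-major over (individual,
dimension) and mapped affinely into the bounds. Compared to uniform draws
the chaotic initial population has a more even low-discrepancy-like spread,
which is what the diversity-based argument for chaotic initialization
amounts to.

A numerical subtlety: in binary floating point the $\mu = 2$ Tent map is
*exactly* computable (doubling and the subtraction $1-x$ for
$x \in [1/2,1]$ are exact), which means every double seed reaches the
absorbing orbit $1/2 \to 1 \to 0$ within about 53 steps as its mantissa
bits are shifted out. Whenever an iterate lands within
$\varepsilon = 10^{-12}$ of $\{0, 1/2, 1\}$ it is nudged into the interior
by $\varepsilon(1+u)$, $u$ a fresh uniform draw (directed away from 1 near
the upper endpoint). Nudge events are recorded in an attribute so sequences
remain auditable, and the exactness below the nudge threshold is what the
test suite exploits: dyadic-rational seeds $p/2^{40}$ reproduce an integer
exact-fraction oracle bit-for-bit over 30 iterates.

**Movement.** Each iteration every individual proposes a step relative to
the current best $x^*$ with fresh draws $m \sim U(0.4, 0.9)$ and
$\beta \sim U(-1, 1)$:
$$x' = x_i + m\,(x^* - x_i) + \min(\beta, 0)\,(x^* - x_i).$$
The $\beta < 0$ branch dampens or reverses the step, providing occasional
repulsion. The widely reprinted form of this rule carries a leading minus
sign that makes the step strictly repulsive from the best for every $m$;
under that convention the optimizer demonstrably fails to converge (on the
package's quadratic recovery benchmark it reaches the $10^{-2}$ fitness bar
in 1 of 10 seeds versus 9 of 10 for the attractive convention), which
contradicts the intended role of the movement strategy. The package
therefore defaults to `movement_sign = "attractive"` and keeps
`"as_printed"` available for side-by-side comparison.

**Gaussian + Tent perturbation.** As a supplementary global-search move,
each individual's retained position is perturbed by per-dimension Gaussian
noise with standard deviation `perturbation_scale` (default 0.1) times the
dimension span, normalized to $[0,1]$, pushed through one Tent step, and
rescaled into the bounds. The Tent step makes this proposal *exploratory*
rather than local — iterated, it wanders densely over the interval — so it
functions as the chaotic escape mechanism, while the movement step provides
exploitation.

**Greedy retention.** Of the two proposals (movement, perturbation) the
better is adopted only if it does not worsen the individual; each position
is therefore its own personal best, which is also the natural base point
for the perturbation. The global best is tracked greedily (ties broken by
lowest index), so the best-fitness history is non-increasing by
construction.

**Pheromone and replacement.** Each individual carries a pheromone
$\varphi_i \in [0,1]$ (initialized at 1) updated by
$\varphi_i \pm f_i / \sum_j f_j$ — up when the attempted move did not
worsen the individual, down otherwise, clipped to $[0,1]$. The update is
scored on the *attempt*: scoring the retained fitness instead would freeze
the pheromones at 1 and disable replacement entirely. When
$\varphi_i \le 0.3$ the individual is rebuilt from three distinct random
partners as $x_{r1} + \sigma (x_{r2} - x_{r3})$ with
$\sigma \sim \mathrm{Bernoulli}(1/2)$, its pheromone reset to 1 — a
differential-evolution-style diversity injection.

Defaults $N = 20$, $T = 50$, $m \in [0.4, 0.9]$, $\beta \in [-1, 1]$,
$\varphi_{th} = 0.3$, $\mu = 2$ are the method's standard settings. Each
iteration costs $2N$ fitness evaluations plus one per replacement, so a
default run is roughly 2000 evaluations.

## Quality metrics

For reference $M$ and image $N$ of size $w \times h$, with 8-bit dynamic
range $L = 255$:

* $\mathrm{MSE} = \frac{1}{wh}\sum_{ij} (M_{ij} - N_{ij})^2$;
* $\mathrm{PSNR} = 10 \log_{10} \bigl( (2^8-1)^2 / \mathrm{MSE} \bigr)$ dB,
  `Inf` for identical images;
* $\mathrm{SSIM} = \frac{(2\mu_x\mu_y + c_1)(2\sigma_{xy} + c_2)}
  {(\mu_x^2+\mu_y^2+c_1)(\sigma_x^2+\sigma_y^2+c_2)}$ with
  $c_1 = (0.01 L)^2$, $c_2 = (0.03 L)^2$, computed from **global** image
  moments (population form). This is the single-window form of the index:
  it is exactly 1 on identity and invariant to identical permutations of
  both images, but it does not localize structure the way the common
  sliding-window SSIM does. The windowed variant is deliberately out of
  scope: the global form is what the fitness optimizes and what the report
  states.
* $\mathrm{ENL} = \mathrm{mean}_i\, \mu_i^2 / (\sigma_i^2 + \varepsilon)$
  over three homogeneous ROIs (population variance,
  $\varepsilon = 10^{-12}$ so constant ROIs yield a large finite value
  flagged as saturated rather than an error — constant phantoms are
  legitimate inputs).
* $\mathrm{EPI}$ = the ratio of summed absolute horizontal central
  differences $|I(x+1,y) - I(x-1,y)|$, noisy over denoised, pooled across
  boundary ROIs. The ratio is reported exactly in this orientation:
  smoothing *reduces* gradients, so values above 1 mean the denoised image
  has weaker edges than the noisy one. No inversion is applied; the
  direction is simply documented. Only the horizontal difference enters
  (no vertical analogue), and ROIs must leave a one-column margin.

Default ROIs: ENL uses three 32×32 squares centered at relative positions
(¼,¼), (¼,¾), (¾,½); EPI uses four 16-pixel-wide frames along the borders,
inset by one pixel. Both are configurable as 0-based half-open rectangles.

## Phantoms and noise

`make_phantom()` generates deterministic test images — piecewise-constant
rectangles, a strictly-monotone-row gradient with a mid-image step edge,
alternating stripes, and soft blobs on a homogeneous background. Each
contains at least one large homogeneous region (so ENL is meaningful) and
at least one step edge (so EPI is meaningful).

`add_noise()` implements the four models at their benchmark defaults:
additive Gaussian with $\sigma = 25$ intensity units; salt-and-pepper
hitting each pixel with probability 0.05, split equally between 0 and 255;
Poisson on the intensity scale with a photons-per-intensity-unit parameter
(1 by default); and speckle as multiplicative Gaussian with variance 0.04.
All are seed-deterministic and clipped to $[0,255]$.

What the phantoms do **not** emulate: anatomical texture, correlated
(structured) noise, scanner-specific modulation-transfer effects, and the
intensity statistics of real CT. Passing the package's tests shows the
machinery is correct and that the optimizer finds chains that denoise
*these* images; absolute metric values on real scans will differ, and the
relative ranking of filter settings may too.

## The ablation harness

`run_ablation()` compares three variants on byte-identical noisy inputs
per seed (paired design): the full method (`BWOA`), no Tent initialization
and no sharpening stage (`BWOA1.0`), and Tent on with sharpening off
(`BWOA2.0`). The two flags are independent in `bwoa_config()`, so other
combinations are configurable. The output table carries the per-run MSE /
PSNR / SSIM / ENL / EPI plus the noisy-input PSNR, whose equality across
variants within a seed witnesses the pairing. No ordering among variants
is asserted by the tests — which variant wins is input-dependent.

## Numerical and design choices

* **Quantization**: images are written as 8-bit using
  round-half-away-from-zero; metrics are computed on the pre-quantization
  real-valued grid, and the run manifest records this.
* **Degenerate inputs**: zero-MSE pairs give `Inf` PSNR; constant ROIs
  saturate ENL; a zero denominator in EPI is an error (degenerate input);
  non-finite fitness aborts the run with a diagnostic.
* **Ties**: the best individual is the lowest index among minima; the Tent
  branch at exactly ½ uses the lower branch (both branches agree there
  anyway).
* **Bounds handling**: positions are clipped after movement; the
  perturbation is contained by construction.
* **Reproducibility**: every random element — the chaotic seed draw, nudge
  perturbations, movement draws, perturbation noise, replacement partners —
  flows from the single run seed; repeated runs are bit-identical, and the
  file-based front end writes byte-identical JSON/CSV under a fixed seed.

## Problem sizes used by the tests

The test suite exercises the full optimizer at the standard $N=20$,
$T=50$ settings on the two-dimensional quadratic recovery benchmark, where
fitness evaluation is free, and uses shortened runs ($T = 6$ on 128×128
phantoms; $T = 2$ with $N = 6$ on 48–64 pixel images for the file-based
and ablation contracts) where each evaluation is a full five-stage filter
chain. The acceptance script runs the complete standard-setting pipeline
on 128×128 phantoms for salt-and-pepper and Gaussian noise. These sizes
were chosen so the whole suite runs comfortably on a laptop while still
covering every code path end to end; nothing in the method depends on the
image being small.

## Known limitations

* Tuning is supervised: a clean reference is required.
* The global-form SSIM can be insensitive to localized structural damage.
* The mean stage has no identity setting (its smallest window is 3×3), so
  the chain cannot represent a strict no-op on textured images; on smooth
  images the near-identity chain changes pixels by well under one intensity
  unit.
* The optimizer is a stochastic heuristic: on a small fraction of seeds it
  stalls short of a tight optimum once the population has contracted (the
  Tent-mapped perturbation is global, not local, so late-stage refinement
  relies on lucky proposals). The quadratic benchmark quantifies this.
* Poisson noise is modeled on the intensity scale; detector gain and offset
  are not modeled.
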