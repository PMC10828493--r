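# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals: plain double
# loops and direct formula evaluation.

reflect_index <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i          # -0 -> 1, -1 -> 2 (edge-repeating)
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

oracle_correlate <- function(img, kernel) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(kernel); kc <- ncol(kernel)
  ri <- (kr - 1) / 2; rj <- (kc - 1) / 2
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (s in seq_len(kr)) for (t in seq_len(kc)) {
      ii <- reflect_index(i + s - 1 - ri, nr)
      jj <- reflect_index(j + t - 1 - rj, nc)
      acc <- acc + kernel[s, t] * img[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

oracle_median <- function(img, ksize) {
  nr <- nrow(img); nc <- ncol(img)
  r <- (ksize - 1) / 2
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- numeric(0)
    for (s in -r:r) for (t in -r:r)
      vals <- c(vals, img[reflect_index(i + s, nr), reflect_index(j + t, nc)])
    out[i, j] <- sort(vals)[(ksize^2 + 1) / 2]
  }
  out
}

oracle_bilateral <- function(img, ksize, sigma_r, sigma_d) {
  nr <- nrow(img); nc <- ncol(img)
  r <- (ksize - 1) / 2
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    num <- 0; den <- 0
    for (s in -r:r) for (t in -r:r) {
      v <- img[reflect_index(i + s, nr), reflect_index(j + t, nc)]
      w <- exp(-(s^2 + t^2) / (2 * sigma_d^2)) *
        exp(-(v - img[i, j])^2 / (2 * sigma_r^2))
      num <- num + w * v
      den <- den + w
    }
    out[i, j] <- num / den
  }
  out
}

oracle_mse <- function(a, b) {
  acc <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    acc <- acc + (a[i, j] - b[i, j])^2
  acc / (nrow(a) * ncol(a))
}

oracle_ssim <- function(x, y, L = 255) {
  n <- length(x)
  mux <- sum(x) / n; muy <- sum(y) / n
  vx <- sum((x - mux)^2) / n; vy <- sum((y - muy)^2) / n
  cxy <- sum((x - mux) * (y - muy)) / n
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  ((2 * mux * muy + c1) * (2 * cxy + c2)) /
    ((mux^2 + muy^2 + c1) * (vx + vy + c2))
}

# pooled horizontal central-difference ratio over a list of rectangles
oracle_epi <- function(noisy, denoised, rois) {
  gsum <- function(img, r) {
    acc <- 0
    for (i in (r[1] + 1):r[3]) for (j in (r[2] + 1):r[4])
      acc <- acc + abs(img[i, j + 1] - img[i, j - 1])
    acc
  }
  num <- sum(sapply(rois, function(r) gsum(noisy, r)))
  den <- sum(sapply(rois, function(r) gsum(denoised, r)))
  num / den
}

# Exact Tent iteration (mu = 2) for a dyadic-rational seed p / 2^k, carried
# in integer numerators (exact in doubles while p < 2^53).
oracle_tent_dyadic <- function(p, k, n) {
  q <- 2^k
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- p / q
    p <- if (2 * p <= q) 2 * p else 2 * (q - p)
  }
  out
}

random_image <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(runif(nr * nc, 0, 255), nr, nc)
}
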