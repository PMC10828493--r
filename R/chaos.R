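#' Tent chaotic map configuration
#'
#' Settings for the Tent map used to seed the optimizer's initial population.
#' The map is chaotic on \[0, 1\] for control parameter `mu = 2`, which is the
#' value used throughout; smaller values shrink the attainable range to
#' \[0, mu/2\].
#'
#' In binary floating point the exact Tent map with `mu = 2` is degenerate:
#' every iteration doubles the value (shifting mantissa bits out), so any
#' double-precision seed reaches the absorbing orbit `1/2 -> 1 -> 0` within
#' about 53 steps. Whenever an iterate lands within `collapse_epsilon` of
#' 0, 1/2 or 1 it is therefore nudged off the absorbing set by a perturbation
#' of size `collapse_epsilon * (1 + u)`, `u` a fresh uniform draw from the run
#' RNG (directed into the interior near the upper endpoint). Nudge events are
#' recorded so sequences remain auditable.
#'
#' @param mu Control parameter, in (0, 2]. Default 2.
#' @param x0 Seed value in (0, 1), or `NULL` to draw one from the current RNG
#'   when a sequence is first requested.
#' @param collapse_epsilon Size of the anti-collapse perturbation. Default
#'   `1e-12`.
#' @return An object of class `"chaos_config"`.
#' @seealso [tent_sequence()], [init_positions()]
#' @export
#' @examples
#' cfg <- chaos_config(x0 = 0.3)
#' tent_sequence(4, cfg)   # 0.3 0.6 0.8 0.4
chaos_config <- function(mu = 2, x0 = NULL, collapse_epsilon = 1e-12) {
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0 || mu > 2)
    stop("`mu` must be a single value in (0, 2]", call. = FALSE)
  if (!is.null(x0)) {
    if (!is.numeric(x0) || length(x0) != 1L || x0 <= 0 || x0 >= 1)
      stop("`x0` must be a single value in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(collapse_epsilon) || collapse_epsilon <= 0)
    stop("`collapse_epsilon` must be positive", call. = FALSE)
  structure(list(mu = mu, x0 = x0, collapse_epsilon = collapse_epsilon),
            class = "chaos_config")
}

#' One step of the Tent map
#'
#' `mu * x` for `x <= 1/2`, `mu * (1 - x)` otherwise. The result lies in
#' \[0, mu/2\]. At `x = 1/2` both branches coincide at `mu/2`.
#'
#' @param x Value(s) in \[0, 1\].
#' @param mu Control parameter in (0, 2].
#' @return Mapped value(s) in \[0, 1\].
#' @export
#' @examples
#' tent_step(0.3, 2)  # 0.6
#' tent_step(0.8, 2)  # 0.4
tent_step <- function(x, mu = 2) {
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0 || mu > 2)
    stop("`mu` must be in (0, 2]", call. = FALSE)
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("`x` must lie in [0, 1]", call. = FALSE)
  ifelse(x <= 0.5, mu * x, mu * (1 - x))
}

#' Generate a Tent chaotic sequence
#'
#' Iterates the Tent map from the configured seed, returning the state
#' sequence (the seed is element 1). Iterates that fall on the absorbing set
#' `{0, 1/2, 1}` (within `collapse_epsilon`) are nudged before use; the
#' positions of nudge events are returned in the `"nudges"` attribute.
#' Nudges consume draws from the run RNG, so sequences are reproducible under
#' a fixed seed.
#'
#' @param n Number of elements to generate (`n >= 1`).
#' @param cfg A [chaos_config()]. If `cfg$x0` is `NULL` a seed is drawn from
#'   the current RNG and recorded in the `"x0"` attribute.
#' @return Numeric vector of length `n` with values in \[0, 1\]; attributes
#'   `"x0"` (seed used) and `"nudges"` (integer indices of nudged elements).
#' @export
tent_sequence <- function(n, cfg = chaos_config()) {
  stopifnot(inherits(cfg, "chaos_config"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("`n` must be >= 1", call. = FALSE)
  n <- as.integer(n)
  eps <- cfg$collapse_epsilon
  x <- if (is.null(cfg$x0)) runif(1, eps, 1 - eps) else cfg$x0
  out <- numeric(n)
  nudges <- integer(0)
  for (k in seq_len(n)) {
    if (min(abs(x - c(0, 0.5, 1))) <= eps) {
      delta <- eps * (1 + runif(1))
      x <- if (x > 0.75) x - delta else x + delta
      nudges <- c(nudges, k)
    }
    out[k] <- x
    if (k < n) x <- tent_step(x, cfg$mu)
  }
  structure(out, x0 = out[1L], nudges = nudges)
}

#' Search-space bounds
#'
#' Per-dimension lower and upper bounds of a continuous search space.
#'
#' @param lower,upper Numeric vectors of equal length with `lower < upper`
#'   element-wise.
#' @return An object of class `"bwoa_bounds"`.
#' @export
bwoa_bounds <- function(lower, upper) {
  if (length(lower) != length(upper) || length(lower) < 1L)
    stop("`lower` and `upper` must be non-empty and of equal length", call. = FALSE)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper))
    stop("bounds must be finite with lower < upper in every dimension", call. = FALSE)
  nm <- names(lower)
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 names = nm), class = "bwoa_bounds")
}

#' Chaotic initialization of the population
#'
#' Maps one Tent sequence of length `n_individuals * n_dims`, consumed in
#' row-major order over (individual, dimension), affinely into the search
#' space: entry (i, d) is `lower[d] + (upper[d] - lower[d]) * c` where `c` is
#' the corresponding chaotic value.
#'
#' @param bounds A [bwoa_bounds()].
#' @param n_individuals,n_dims Population size and dimensionality (`>= 1`).
#'   `n_dims` must equal the number of dimensions in `bounds`.
#' @param cfg A [chaos_config()].
#' @return `n_individuals x n_dims` matrix with every entry inside its
#'   dimension's bounds; the Tent sequence used is attached as attribute
#'   `"chaos"`.
#' @export
init_positions <- function(bounds, n_individuals, n_dims, cfg = chaos_config()) {
  stopifnot(inherits(bounds, "bwoa_bounds"))
  if (n_dims != length(bounds$lower))
    stop("`n_dims` must match the dimensionality of `bounds`", call. = FALSE)
  if (n_individuals < 1 || n_dims < 1) stop("counts must be >= 1", call. = FALSE)
  cs <- tent_sequence(n_individuals * n_dims, cfg)
  cm <- matrix(cs, nrow = n_individuals, ncol = n_dims, byrow = TRUE)
  span <- bounds$upper - bounds$lower
  pos <- sweep(sweep(cm, 2, span, "*"), 2, bounds$lower, "+")
  colnames(pos) <- bounds$names
  structure(pos, chaos = cs)
}
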