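# YAML configuration: one file drives the optimizer, chaos map, search
# bounds and ROIs for the command-line tools.

#' Default configuration
#'
#' The full configuration as a plain list, mirroring the YAML schema used by
#' [read_config()]: sections `chaos` (`mu`, `x0`, `collapse_epsilon`),
#' `bwoa` (optimizer constants and variant flags), `bounds`
#' (`lower` / `upper`, 8 values each) and `rois` (`enl` / `epi`, lists of
#' 4-integer 0-based half-open rectangles; `null` means the built-in
#' defaults for the image at hand).
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  b <- default_bounds()
  list(
    chaos = list(mu = 2, x0 = NULL, collapse_epsilon = 1e-12),
    bwoa = list(population_size = 20L, max_iterations = 50L,
                m_range = c(0.4, 0.9), beta_range = c(-1, 1),
                pheromone_threshold = 0.3, lambda_weight = 0.5,
                perturbation_scale = 0.1, use_tent = TRUE,
                use_sharpen = TRUE, movement_sign = "attractive"),
    bounds = list(lower = as.list(b$lower), upper = as.list(b$upper)),
    rois = list(enl = NULL, epi = NULL)
  )
}

#' Read a YAML configuration
#'
#' Loads a YAML file and merges it over [default_config()]; `path = NULL`
#' returns the defaults.
#'
#' @param path Path to a YAML file, or `NULL`.
#' @return Nested named list in the [default_config()] schema.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (section in intersect(names(user), names(cfg))) {
    if (is.list(cfg[[section]]) && is.list(user[[section]]))
      cfg[[section]] <- utils::modifyList(cfg[[section]], user[[section]])
    else cfg[[section]] <- user[[section]]
  }
  cfg
}

# Turn the plain config list into the package's typed objects.
config_objects <- function(cfg) {
  chaos <- chaos_config(mu = cfg$chaos$mu, x0 = cfg$chaos$x0,
                        collapse_epsilon = cfg$chaos$collapse_epsilon)
  bw <- cfg$bwoa
  config <- bwoa_config(
    population_size = bw$population_size, max_iterations = bw$max_iterations,
    m_range = unlist(bw$m_range), beta_range = unlist(bw$beta_range),
    pheromone_threshold = bw$pheromone_threshold,
    lambda_weight = bw$lambda_weight,
    perturbation_scale = bw$perturbation_scale,
    use_tent = bw$use_tent, use_sharpen = bw$use_sharpen,
    movement_sign = bw$movement_sign, chaos = chaos
  )
  lower <- unlist(cfg$bounds$lower)
  upper <- unlist(cfg$bounds$upper)
  bounds <- bwoa_bounds(lower, upper)
  parse_rois <- function(x) if (is.null(x)) NULL else lapply(x, function(r) do.call(roi, as.list(unlist(r))))
  list(config = config, bounds = bounds,
       enl_rois = parse_rois(cfg$rois$enl), epi_rois = parse_rois(cfg$rois$epi))
}
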