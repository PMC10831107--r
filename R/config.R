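#' Default pipeline configuration
#'
#' One structured configuration drives the whole pipeline: input mode,
#' grid and generator parameters (synthetic mode), the ecotype list or
#' E_o sweep, layers and regions to analyze, significance level, skill
#' mode and seed. The default is the desk-scale synthetic world: 6 x 6
#' horizontal cells, 10 depth levels over 0--600 m, 64 initialization
#' years, 10 lead years, 10 members, and an E_o sweep from -0.2 to 1.0 eV
#' in 0.1 eV steps at A_c = 10 atm^-1.
#'
#' @param seed integer seed for all randomness.
#' @return a named list of class `run_config`.
#' @export
default_config <- function(seed = 42) {
  structure(list(
    mode = "synthetic",
    paths = list(reconstruction = NULL, forecasts = NULL),
    grid = list(n_lat = 6, n_lon = 6, depth_min = 0, depth_max = 600,
                n_depth = 10),
    synth = list(n_members = 10, n_inits = 64, n_leads = 10,
                 start_year = 1954),
    sweep = list(eo_min = -0.2, eo_max = 1.0, eo_step = 0.1, A_c = 10),
    traits = NULL,            # explicit list of (species, A_c, E_o) rows
    layers = c("upper", "lower"),
    regions = NULL,           # default: all labeled regions on the grid
    alpha = 0.05,
    skill_mode = "region-series",
    phi_bar = "phi_of_mean",
    write_netcdf = FALSE,
    seed = seed), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields present in the file override the defaults of
#' [default_config]; everything else keeps its default. The configuration
#' is validated before use.
#'
#' @param path YAML file path.
#' @return a validated `run_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_config()), user)
  validate_config(structure(cfg, class = "run_config"))
}

#' Validate a pipeline configuration
#'
#' @param cfg a `run_config` list.
#' @return the configuration, invisibly, after checks: the sweep step must
#'   divide the span, A_c must be positive, the significance level must
#'   lie in (0, 1), and the skill mode must be known.
#' @export
validate_config <- function(cfg) {
  sw <- cfg$sweep
  if (!is.null(sw)) {
    span <- sw$eo_max - sw$eo_min
    k <- span / sw$eo_step
    if (abs(k - round(k)) > 1e-8)
      stopf("sweep step %g does not divide the span [%g, %g]",
            sw$eo_step, sw$eo_min, sw$eo_max)
    if (sw$A_c <= 0) stopf("sweep A_c must be positive")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stopf("significance level must lie in (0, 1)")
  if (!cfg$skill_mode %in% c("region-series", "per-cell"))
    stopf("unknown skill mode '%s'", cfg$skill_mode)
  if (!cfg$mode %in% c("synthetic", "netcdf"))
    stopf("unknown input mode '%s'", cfg$mode)
  invisible(cfg)
}

#' Ecotype list implied by a configuration
#'
#' Either the explicit trait rows of `cfg$traits`, or the E_o sweep
#' (shared A_c) when none are given.
#'
#' @param cfg a `run_config`.
#' @return a named list of [trait_set] objects.
#' @export
config_traits <- function(cfg) {
  if (!is.null(cfg$traits)) {
    out <- lapply(cfg$traits, function(tr)
      trait_set(A_c = tr$A_c, E_o = tr$E_o, species = tr$species %||% NULL))
    return(stats::setNames(out, vapply(out, `[[`, "", "species")))
  }
  sw <- cfg$sweep
  eo <- round(seq(sw$eo_min, sw$eo_max, by = sw$eo_step), 10)
  out <- lapply(eo, function(e) trait_set(A_c = sw$A_c, E_o = e))
  stats::setNames(out, sprintf("Eo_%+.1f", eo))
}
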