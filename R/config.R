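## Run configuration: a flat, human-editable key-value file (YAML) with
## units spelled out in the key names so mm/kV/uL-min inputs cannot be
## confused with the SI quantities used internally.

.required_config_keys <- c(
  "needle_inner_diameter_mm", "needle_outer_diameter_mm", "gap_mm",
  "plate_half_width_mm", "plate_thickness_mm", "needle_protrusion_mm",
  "domain_half_width_mm", "domain_height_above_mm",
  "potential_kv", "comparison_potential_kv", "plate_potential_kv",
  "spacing_um", "mode", "outer_boundary",
  "flow_ul_min", "fluid_density_kg_m3", "surface_tension_n_m", "seed")

#' Default run configuration
#'
#' The study's operating point: the 18G needle / 70 mm gap device solved
#' axisymmetrically at 100 um spacing, 15 kV with a 10 kV comparison
#' solve, 200 uL/min flow and water-like fluid properties.
#'
#' @return a named list of configuration values (units in the key names)
#' @examples
#' cfg <- espray_default_config()
#' cfg$gap_mm
#' @export
espray_default_config <- function() {
  list(needle_inner_diameter_mm = 0.838, needle_outer_diameter_mm = 1.27,
       gap_mm = 70, plate_half_width_mm = 30, plate_thickness_mm = 1.5,
       needle_protrusion_mm = 30, domain_half_width_mm = 30,
       domain_height_above_mm = 10,
       potential_kv = 15, comparison_potential_kv = 10,
       plate_potential_kv = 0,
       spacing_um = 100, mode = "axisymmetric", outer_boundary = "neumann",
       flow_ul_min = 200, fluid_density_kg_m3 = 1000,
       surface_tension_n_m = 0.07, seed = 1L)
}

.config_error <- function(msg) {
  stop(structure(class = c("espray_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Validate a run configuration
#'
#' @param config named list of configuration values
#' @return the config, invisibly, after validation; a missing key raises
#'   an error of class `espray_config_error` naming the key
#' @export
validate_config <- function(config) {
  missing_keys <- setdiff(.required_config_keys, names(config))
  if (length(missing_keys))
    .config_error(sprintf("config is missing key(s): %s",
                          paste(missing_keys, collapse = ", ")))
  num <- setdiff(.required_config_keys, c("mode", "outer_boundary"))
  bad <- num[!vapply(config[num], function(v)
    is.numeric(v) && length(v) == 1 && is.finite(v), logical(1))]
  if (length(bad))
    .config_error(sprintf("config key(s) not single finite numbers: %s",
                          paste(bad, collapse = ", ")))
  if (!config$mode %in% c("axisymmetric", "planar"))
    .config_error("config key 'mode' must be 'axisymmetric' or 'planar'")
  if (!config$outer_boundary %in% c("neumann", "grounded"))
    .config_error("config key 'outer_boundary' must be 'neumann' or 'grounded'")
  invisible(config)
}

#' Read / write a run configuration file
#'
#' @param path YAML file of flat key-value pairs
#' @return `read_run_config()` returns the validated config list;
#'   `write_run_config()` returns `path` invisibly
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) .config_error(sprintf("config file not found: %s", path))
  config <- yaml::read_yaml(path)
  validate_config(config)
  config
}

#' @param config a config list, e.g. [espray_default_config()]
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(config, path)
  invisible(path)
}

# config -> domain objects
.config_geometry <- function(config) {
  device_geometry(
    needle_inner_diameter = config$needle_inner_diameter_mm * 1e-3,
    needle_outer_diameter = config$needle_outer_diameter_mm * 1e-3,
    gap = config$gap_mm * 1e-3,
    plate_half_width = config$plate_half_width_mm * 1e-3,
    plate_thickness = config$plate_thickness_mm * 1e-3,
    needle_protrusion = config$needle_protrusion_mm * 1e-3,
    domain_half_width = config$domain_half_width_mm * 1e-3,
    domain_height_above = config$domain_height_above_mm * 1e-3)
}

.config_potential <- function(config, kv = config$potential_kv) {
  operating_potential(applied = kv * 1e3,
                      plate = config$plate_potential_kv * 1e3)
}

.config_fluid <- function(config) {
  fluid_properties(density = config$fluid_density_kg_m3,
                   surface_tension = config$surface_tension_n_m)
}
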