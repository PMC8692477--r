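#' Working-fluid properties
#'
#' Density and surface tension of the sprayed solution. The cell-carrying
#' pullulan/gelatin/media solution is dilute, so water-like defaults are
#' used; both are configuration-exposed. The vacuum permittivity and
#' standard gravity ride along as immutable constants.
#'
#' @param density fluid density (kg/m^3)
#' @param surface_tension surface tension (N/m)
#' @return an object of class `espray_fluid`
#' @examples
#' fluid_properties()
#' @export
fluid_properties <- function(density = 1000, surface_tension = 0.07) {
  if (!is.finite(density) || density <= 0) .stopf("density must be > 0")
  if (!is.finite(surface_tension) || surface_tension <= 0)
    .stopf("surface_tension must be > 0")
  structure(list(density = density, surface_tension = surface_tension,
                 eps0 = .const$eps0, g = .const$g),
            class = "espray_fluid")
}

#' Operating conditions of the electrospray
#'
#' @param applied_potential needle potential (V); the study uses 10e3 / 15e3
#' @param flow_rate volumetric flow rate (m^3/s); alternatively give
#'   `flow_ul_min`
#' @param flow_ul_min flow rate in uL/min (the study uses 200)
#' @param geometry a [device_geometry()]
#' @param meniscus_diameter meniscus diameter (m); defaults to the needle
#'   outer diameter
#' @return an object of class `espray_conditions`
#' @examples
#' operating_conditions(15e3, flow_ul_min = 200)
#' @export
operating_conditions <- function(applied_potential = 15e3,
                                 flow_rate = NULL, flow_ul_min = 200,
                                 geometry = device_geometry(),
                                 meniscus_diameter = NULL) {
  stopifnot(inherits(geometry, "espray_geometry"))
  if (is.null(flow_rate)) flow_rate <- ul_min_to_m3s(flow_ul_min)
  if (!is.finite(flow_rate) || flow_rate <= 0) .stopf("flow rate must be > 0")
  if (!is.finite(applied_potential) || applied_potential <= 0)
    .stopf("applied potential must be > 0")
  if (is.null(meniscus_diameter))
    meniscus_diameter <- geometry$needle_outer_diameter
  structure(list(applied_potential = applied_potential,
                 flow_rate = flow_rate, geometry = geometry,
                 meniscus_diameter = meniscus_diameter),
            class = "espray_conditions")
}

#' Order-of-magnitude force scales on the meniscus
#'
#' Evaluates the four scales governing drop formation at the capillary tip:
#' the electric force `eps0 * phi^2`, the gravitational force
#' `rho * Do^3 * g`, the momentum per unit time injected by the flow
#' `rho * Q^2 / Di^2` (an inertial scale, not a force on a specific body),
#' and the restoring surface tension `Do * gamma`. Their ratios — chiefly
#' electric over surface tension — set the spraying mode.
#'
#' @param fluid a [fluid_properties()]
#' @param op an [operating_conditions()]
#' @return an object of class `espray_force_scales` with the four scales
#'   (N) and each scale normalised by the surface-tension scale
#' @examples
#' force_scales(fluid_properties(), operating_conditions(15e3))
#' @export
force_scales <- function(fluid = fluid_properties(),
                         op = operating_conditions()) {
  stopifnot(inherits(fluid, "espray_fluid"), inherits(op, "espray_conditions"))
  geom <- op$geometry
  d_i <- geom$needle_inner_diameter
  d_o <- geom$needle_outer_diameter
  f_electric <- fluid$eps0 * op$applied_potential^2
  f_gravity <- fluid$density * d_o^3 * fluid$g
  p_inertial <- fluid$density * op$flow_rate^2 / d_i^2
  f_surface_tension <- d_o * fluid$surface_tension
  ratios <- c(electric = f_electric, gravity = f_gravity,
              inertial = p_inertial,
              surface_tension = f_surface_tension) / f_surface_tension
  structure(list(f_electric = f_electric, f_gravity = f_gravity,
                 p_inertial = p_inertial,
                 f_surface_tension = f_surface_tension,
                 ratios = ratios, fluid = fluid, op = op),
            class = "espray_force_scales")
}

#' @export
print.espray_force_scales <- function(x, ...) {
  cat(sprintf("<espray force scales> %.0f kV, %.0f uL/min\n",
              x$op$applied_potential / 1e3, x$op$flow_rate / 1e-9 * 60))
  cat(sprintf("  electric        : %.3e N  (%.1f x surface tension)\n",
              x$f_electric, x$ratios[["electric"]]))
  cat(sprintf("  gravity         : %.3e N  (%.2f x)\n",
              x$f_gravity, x$ratios[["gravity"]]))
  cat(sprintf("  inertial (flow) : %.3e N  (%.2e x)\n",
              x$p_inertial, x$ratios[["inertial"]]))
  cat(sprintf("  surface tension : %.3e N\n", x$f_surface_tension))
  invisible(x)
}

#' Classify the electrospraying mode
#'
#' Applies a dimensionless threshold rule to the electric/surface-tension
#' force ratio: at or above `threshold` the meniscus is dominated by
#' electric stresses and operates in the micro-dripping mode (droplets much
#' smaller than the nozzle); below it, plain dripping. An optional upper
#' threshold marks the oscillating micro-dripping regime; it is disabled by
#' default because no quantitative boundary is established for this device.
#'
#' @param report an [force_scales()] report
#' @param threshold electric/surface-tension ratio at which micro-dripping
#'   begins
#' @param oscillating_threshold optional ratio above which the mode is
#'   labelled oscillating micro-dripping (`NULL` disables)
#' @return an object of class `espray_mode`: the mode label, a rationale
#'   string naming the ratio, and the droplet-diameter bounds for
#'   micro-dripping
#' @examples
#' classify_mode(force_scales(op = operating_conditions(15e3)))
#' @export
classify_mode <- function(report, threshold = 1,
                          oscillating_threshold = NULL) {
  stopifnot(inherits(report, "espray_force_scales"))
  ratio <- report$f_electric / report$f_surface_tension
  mode <- if (!is.null(oscillating_threshold) && ratio >= oscillating_threshold)
    "oscillating micro-dripping"
  else if (ratio >= threshold) "micro-dripping" else "dripping"
  d_o <- report$op$geometry$needle_outer_diameter
  bounds <- if (mode == "micro-dripping") c(0.05, 0.85) * d_o
            else c(NA_real_, NA_real_)
  rationale <- sprintf(
    "electric/surface-tension force ratio = %.1f %s threshold %.2g",
    ratio, if (ratio >= threshold) ">=" else "<", threshold)
  structure(list(mode = mode, rationale = rationale, ratio = ratio,
                 droplet_diameter_bounds = bounds),
            class = "espray_mode")
}

#' @export
print.espray_mode <- function(x, ...) {
  cat(sprintf("<espray mode> %s (%s)\n", x$mode, x$rationale))
  if (!anyNA(x$droplet_diameter_bounds))
    cat(sprintf("  droplet diameter bounds: %.1f - %.1f um\n",
                x$droplet_diameter_bounds[1] * 1e6,
                x$droplet_diameter_bounds[2] * 1e6))
  invisible(x)
}

#' Droplet-diameter bounds in the micro-dripping mode
#'
#' In micro-dripping the detached droplets are much smaller than the
#' nozzle: diameters fall between 0.05 and 0.85 of the needle outer
#' diameter. For the 1.27 mm needle this is 63.5 - 1079.5 um, bracketing
#' the observed 200 - 300 um droplets.
#'
#' @param geometry a [device_geometry()]
#' @return length-2 numeric, lower and upper diameter bound (m)
#' @examples
#' droplet_diameter_bounds(device_geometry()) * 1e6
#' @export
droplet_diameter_bounds <- function(geometry = device_geometry()) {
  stopifnot(inherits(geometry, "espray_geometry"))
  c(0.05, 0.85) * geometry$needle_outer_diameter
}

#' Field and shear exposure of cells in transit
#'
#' Summarises what a cell experiences on its way out of the needle: the
#' mean exit velocity `Q / (pi (Di/2)^2)`, the residence time in the wetted
#' bore (bore volume over flow rate, with the needle protrusion as the
#' wetted length), and the electric field along the transit path — its
#' peak over the bore and exit region, and its value at the centre of the
#' bore opening.
#'
#' @param op an [operating_conditions()]
#' @param field an `espray_field_map` solved for the same geometry and
#'   potential
#' @param wetted_length wetted bore length for the residence time (m);
#'   defaults to the needle protrusion
#' @return an object of class `espray_exposure`
#' @export
exposure_report <- function(op, field, wetted_length = NULL) {
  stopifnot(inherits(op, "espray_conditions"),
            inherits(field, "espray_field_map"))
  geom <- op$geometry
  grid <- field$grid
  if (!is.null(grid$geometry) && !identical(grid$geometry, geom))
    .stopf("field map was solved for a different geometry")
  if (!is.null(grid$geometry) &&
      !isTRUE(all.equal(grid$potential$applied, op$applied_potential)))
    .stopf("field map was solved at %.0f V but conditions specify %.0f V",
           grid$potential$applied, op$applied_potential)
  if (is.null(wetted_length)) wetted_length <- geom$needle_protrusion
  bore_area <- pi * (geom$needle_inner_diameter / 2)^2
  v_exit <- op$flow_rate / bore_area
  t_res <- bore_area * wetted_length / op$flow_rate

  # transit path: inside the bore and across the gap, within the bore radius
  ri <- geom$needle_inner_diameter / 2
  in_path <- abs(grid$r) <= ri + grid$spacing / 2
  on_gap <- grid$z >= -geom$needle_protrusion - grid$spacing / 2 &
    grid$z <= geom$gap + grid$spacing / 2
  mag <- field$magnitude[in_path, on_gap, drop = FALSE]
  if (all(is.na(mag))) .stopf("no free nodes on the transit path")
  peak <- max(mag, na.rm = TRUE)
  loc <- which(field$magnitude == peak &
                 outer(in_path, on_gap), arr.ind = TRUE)[1, ]
  i0 <- .axis_index(grid); k0 <- .tip_plane_index(grid)
  e_exit <- field$magnitude[i0, k0]
  structure(list(mean_exit_velocity = v_exit,
                 needle_residence_time = t_res,
                 peak_field_on_path = peak,
                 peak_location = c(r = grid$r[loc[["row"]]],
                                   z = grid$z[loc[["col"]]]),
                 field_at_exit_center = e_exit,
                 wetted_length = wetted_length, op = op),
            class = "espray_exposure")
}

#' @export
print.espray_exposure <- function(x, ...) {
  cat("<espray cell-exposure report>\n")
  cat(sprintf("  mean exit velocity    : %.2f mm/s\n",
              x$mean_exit_velocity * 1e3))
  cat(sprintf("  bore residence time   : %.2f s (wetted length %.0f mm)\n",
              x$needle_residence_time, x$wetted_length * 1e3))
  cat(sprintf("  peak |E| on path      : %.3f MV/m at (r = %.0f um, z = %.2f mm)\n",
              x$peak_field_on_path / 1e6, x$peak_location[["r"]] * 1e6,
              x$peak_location[["z"]] * 1e3))
  cat(sprintf("  |E| at bore exit centre: %.3f MV/m\n",
              x$field_at_exit_center / 1e6))
  invisible(x)
}
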