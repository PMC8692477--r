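#' Needle-plate electrospray device geometry
#'
#' Describes the electrode layout of the needle-plate device: a stainless
#' steel capillary needle facing a grounded collector plate across an air
#' gap. Defaults are the 18G needle (0.838 mm bore, 1.27 mm outer diameter)
#' spraying across a 70 mm gap onto a 60 x 60 x 1.5 mm plate. All lengths
#' are in metres; use the `*_mm` keys of [read_run_config()] for mm input.
#'
#' The simulation box extends `domain_half_width` laterally from the axis
#' and `domain_height_above` above the needle entry; the needle protrudes
#' `needle_protrusion` into the box with its tip at the coordinate origin
#' (z = 0, z increasing towards the plate).
#'
#' @param needle_inner_diameter bore diameter (m)
#' @param needle_outer_diameter outer diameter (m)
#' @param gap tip-to-plate distance (m)
#' @param plate_half_width half-width of the collector plate (m)
#' @param plate_thickness plate thickness (m)
#' @param needle_protrusion exposed needle length above the tip (m)
#' @param domain_half_width lateral half-extent of the simulation box (m)
#' @param domain_height_above box extent above the needle entry (m)
#' @return an object of class `espray_geometry`
#' @examples
#' geom <- device_geometry()
#' geom$gap
#' @export
device_geometry <- function(needle_inner_diameter = 0.838e-3,
                            needle_outer_diameter = 1.27e-3,
                            gap = 70e-3,
                            plate_half_width = 30e-3,
                            plate_thickness = 1.5e-3,
                            needle_protrusion = 30e-3,
                            domain_half_width = 30e-3,
                            domain_height_above = 10e-3) {
  lens <- c(needle_inner_diameter = needle_inner_diameter,
            needle_outer_diameter = needle_outer_diameter,
            gap = gap, plate_half_width = plate_half_width,
            plate_thickness = plate_thickness,
            needle_protrusion = needle_protrusion,
            domain_half_width = domain_half_width,
            domain_height_above = domain_height_above)
  if (any(!is.finite(lens)) || any(lens <= 0))
    .stopf("all geometry lengths must be finite and > 0")
  if (needle_inner_diameter >= needle_outer_diameter)
    .stopf("needle_inner_diameter (%g m) must be smaller than needle_outer_diameter (%g m)",
           needle_inner_diameter, needle_outer_diameter)
  if (needle_outer_diameter / 2 >= domain_half_width)
    .stopf("needle does not fit laterally in the domain")
  if (plate_half_width > domain_half_width) {
    .warnf("plate_half_width (%g m) exceeds domain_half_width (%g m); plate clipped",
           plate_half_width, domain_half_width)
    plate_half_width <- domain_half_width
  }
  structure(list(needle_inner_diameter = needle_inner_diameter,
                 needle_outer_diameter = needle_outer_diameter,
                 gap = gap, plate_half_width = plate_half_width,
                 plate_thickness = plate_thickness,
                 needle_protrusion = needle_protrusion,
                 domain_half_width = domain_half_width,
                 domain_height_above = domain_height_above),
            class = "espray_geometry")
}

#' @export
print.espray_geometry <- function(x, ...) {
  cat("<espray device geometry>\n")
  cat(sprintf("  needle: %.3f / %.3f mm (bore / outer), protruding %.1f mm\n",
              x$needle_inner_diameter * 1e3, x$needle_outer_diameter * 1e3,
              x$needle_protrusion * 1e3))
  cat(sprintf("  gap: %.1f mm; plate: %.0f x %.1f mm (half-width x thickness)\n",
              x$gap * 1e3, x$plate_half_width * 1e3, x$plate_thickness * 1e3))
  cat(sprintf("  domain: +/-%.0f mm lateral, %.0f mm above needle entry\n",
              x$domain_half_width * 1e3, x$domain_height_above * 1e3))
  invisible(x)
}

#' Operating potential of the device
#'
#' @param applied potential on the needle (V); the study uses 10e3 and 15e3
#' @param plate potential on the collector plate (V), grounded by default
#' @return an object of class `espray_potential`
#' @examples
#' operating_potential(15e3)
#' @export
operating_potential <- function(applied = 15e3, plate = 0) {
  if (!is.finite(applied) || !is.finite(plate))
    .stopf("potentials must be finite")
  if (applied == plate)
    .stopf("applied potential must differ from the plate potential")
  structure(list(applied = applied, plate = plate), class = "espray_potential")
}

#' @export
print.espray_potential <- function(x, ...) {
  cat(sprintf("<espray potential> needle %.1f kV, plate %.1f kV\n",
              x$applied / 1e3, x$plate / 1e3))
  invisible(x)
}
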