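#' Discretise the device cross-section onto a solver grid
#'
#' Rasterises the needle annulus and the collector plate onto a uniform
#' finite-difference grid and attaches their Dirichlet potentials. In
#' `axisymmetric` mode the grid covers the half-plane r >= 0 with the
#' cylindrical Laplacian and the regularity condition at r = 0; in `planar`
#' mode it covers the full Cartesian cross-section x in [-W, W]. z = 0 is
#' the needle-tip plane and z increases towards the plate. Open (non-
#' conductor) boundaries carry homogeneous Neumann conditions unless
#' `outer_boundary = "grounded"` puts the lateral and top edges at the plate
#' potential.
#'
#' The spacing must resolve the needle bore: at least 8 nodes across the
#' bore diameter, i.e. `spacing <= needle_inner_diameter / 8`.
#'
#' @param geometry a [device_geometry()]
#' @param potential an [operating_potential()]
#' @param spacing node spacing (m); default 100 um
#' @param mode `"axisymmetric"` (default) or `"planar"`
#' @param outer_boundary `"neumann"` (default) or `"grounded"`
#' @return an object of class `espray_grid` with the node coordinates,
#'   conductor mask (0 free, 1 needle, 2 plate) and Dirichlet values
#' @examples
#' g <- build_grid(device_geometry(), operating_potential(15e3),
#'                 spacing = 100e-6)
#' g$n_r * g$n_z
#' @export
build_grid <- function(geometry, potential, spacing = 100e-6,
                       mode = c("axisymmetric", "planar"),
                       outer_boundary = c("neumann", "grounded")) {
  stopifnot(inherits(geometry, "espray_geometry"),
            inherits(potential, "espray_potential"))
  mode <- match.arg(mode)
  outer_boundary <- match.arg(outer_boundary)
  if (!is.finite(spacing) || spacing <= 0) .stopf("spacing must be > 0")
  max_spacing <- geometry$needle_inner_diameter / 8
  if (spacing > max_spacing)
    .stopf(paste0("spacing %g m is too coarse to resolve the needle bore: ",
                  "need spacing <= needle_inner_diameter / 8 = %g m"),
           spacing, max_spacing)

  ri <- geometry$needle_inner_diameter / 2
  ro <- geometry$needle_outer_diameter / 2
  w  <- geometry$domain_half_width
  zmin <- -(geometry$needle_protrusion + geometry$domain_height_above)
  zmax <- geometry$gap + geometry$plate_thickness

  # node coordinates are exact integer multiples of the spacing, with the
  # axis (r = 0) and the tip plane (z = 0) on nodes
  n_lat <- round(w / spacing)
  r <- if (mode == "axisymmetric") (0:n_lat) * spacing
       else (-n_lat:n_lat) * spacing
  z <- (round(zmin / spacing):round(zmax / spacing)) * spacing
  n_r <- length(r); n_z <- length(z)
  eps <- spacing * 1e-6

  mask <- matrix(0L, n_r, n_z)
  in_wall <- abs(r) >= ri - eps & abs(r) <= ro + eps
  in_prot <- z >= -geometry$needle_protrusion - eps & z <= eps
  mask[in_wall, in_prot] <- 1L
  in_plate_r <- abs(r) <= geometry$plate_half_width + eps
  in_plate_z <- z >= geometry$gap - eps & z <= geometry$gap + geometry$plate_thickness + eps
  mask[in_plate_r, in_plate_z] <- 2L
  if (outer_boundary == "grounded") {
    sides <- if (mode == "planar") c(1L, n_r) else n_r
    mask[sides, ] <- pmax(mask[sides, ], 2L)   # lateral wall(s)
    mask[, 1L] <- pmax(mask[, 1L], 2L)         # top edge above needle entry
  }
  if (!any(mask == 1L)) .stopf("needle wall rasterised to no nodes; refine spacing")
  if (!any(mask == 2L)) .stopf("plate rasterised to no nodes")

  structure(list(mode = mode, outer_boundary = outer_boundary,
                 spacing = spacing, r = r, z = z, n_r = n_r, n_z = n_z,
                 mask = mask,
                 dirichlet = c(needle = potential$applied,
                               plate = potential$plate),
                 geometry = geometry, potential = potential),
            class = "espray_grid")
}

#' Parallel-plate reference grid
#'
#' Builds a grid with two full-width plane electrodes a distance `gap`
#' apart and no needle. The closed-form interior field |E| = V / gap makes
#' this the standard correctness check for the solver.
#'
#' @param gap electrode separation (m)
#' @param potential an [operating_potential()]
#' @param spacing node spacing (m)
#' @param half_width lateral half-extent (m)
#' @param mode grid formulation, as in [build_grid()]
#' @return an `espray_grid`
#' @examples
#' g <- parallel_plate_grid(70e-3, operating_potential(15e3), spacing = 1e-3)
#' @export
parallel_plate_grid <- function(gap, potential, spacing,
                                half_width = 10e-3,
                                mode = c("axisymmetric", "planar")) {
  stopifnot(inherits(potential, "espray_potential"))
  mode <- match.arg(mode)
  if (!is.finite(gap) || gap <= 0 || !is.finite(spacing) || spacing <= 0)
    .stopf("gap and spacing must be > 0")
  n_lat <- round(half_width / spacing)
  r <- if (mode == "axisymmetric") (0:n_lat) * spacing
       else (-n_lat:n_lat) * spacing
  z <- (-1:(round(gap / spacing) + 1)) * spacing
  n_r <- length(r); n_z <- length(z)
  mask <- matrix(0L, n_r, n_z)
  mask[, z <= 0] <- 1L          # charged electrode at z <= 0
  # grounded electrode from the node nearest the gap outward
  mask[, z >= round(gap / spacing) * spacing - spacing / 2] <- 2L
  structure(list(mode = mode, outer_boundary = "neumann",
                 spacing = spacing, r = r, z = z, n_r = n_r, n_z = n_z,
                 mask = mask,
                 dirichlet = c(needle = potential$applied,
                               plate = potential$plate),
                 geometry = NULL, potential = potential),
            class = "espray_grid")
}

#' @export
print.espray_grid <- function(x, ...) {
  cat(sprintf("<espray solver grid> %s, %d x %d nodes, spacing %.0f um\n",
              x$mode, x$n_r, x$n_z, x$spacing * 1e6))
  cat(sprintf("  conductor nodes: %d needle, %d plate; %d free\n",
              sum(x$mask == 1L), sum(x$mask == 2L), sum(x$mask == 0L)))
  invisible(x)
}

# two grids discretise the same problem (same stencil and electrodes)
.same_grid <- function(a, b) {
  isTRUE(a$mode == b$mode) && isTRUE(a$spacing == b$spacing) &&
    a$n_r == b$n_r && a$n_z == b$n_z && identical(a$mask, b$mask)
}
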