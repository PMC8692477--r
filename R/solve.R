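## Finite-volume assembly of the Poisson problem on an espray_grid.
##
## Faces between adjacent nodes carry conductances g = (face area)/(node
## distance) per unit azimuthal angle (axisymmetric) or unit depth (planar):
## axisymmetric radial face g = r_{i+1/2}, vertical face g = r_i (the axis
## control volume is a disc of radius h/2, giving g = h/8 and the r = 0
## regularity condition); planar faces g = 1. The resulting matrix is a
## symmetric M-matrix, so the discrete maximum principle holds by
## construction for zero charge density.
.assemble_poisson <- function(grid, charge_density = NULL) {
  h <- grid$spacing; n_r <- grid$n_r; n_z <- grid$n_z
  mask <- grid$mask
  free <- mask == 0L
  nfree <- sum(free)
  if (nfree == 0L) .stopf("grid has no free nodes")
  fmap <- integer(n_r * n_z)
  fmap[free] <- seq_len(nfree)
  idx <- matrix(seq_len(n_r * n_z), n_r, n_z)
  axis <- grid$mode == "axisymmetric"
  rad <- abs(grid$r)

  # vertical-face conductance per radial row; radial-face conductance per face
  g_vert <- if (axis) { g <- rad; g[rad == 0] <- h / 8; g } else rep(1, n_r)
  g_rad  <- if (axis) rad[-n_r] + h / 2 else rep(1, n_r - 1)

  phi_bc <- grid$dirichlet

  face_terms <- function(ia, ib, g) {
    fa <- free[ia]; fb <- free[ib]; both <- fa & fb
    list(i  = c(fmap[ia[both]], fmap[ib[both]]),
         j  = c(fmap[ib[both]], fmap[ia[both]]),
         x  = c(-g[both], -g[both]),
         di = c(fmap[ia[fa]], fmap[ib[fb]]),
         dx = c(g[fa], g[fb]),
         bi = c(fmap[ia[fa & !fb]], fmap[ib[!fa & fb]]),
         bx = c(g[fa & !fb] * phi_bc[mask[ib[fa & !fb]]],
                g[!fa & fb] * phi_bc[mask[ia[!fa & fb]]]))
  }
  Fr <- face_terms(as.vector(idx[-n_r, ]), as.vector(idx[-1, ]),
                   rep(g_rad, n_z))
  Fz <- face_terms(as.vector(idx[, -n_z]), as.vector(idx[, -1]),
                   rep(g_vert, n_z - 1))

  A <- Matrix::sparseMatrix(i = c(Fr$i, Fz$i, Fr$di, Fz$di),
                            j = c(Fr$j, Fz$j, Fr$di, Fz$di),
                            x = c(Fr$x, Fz$x, Fr$dx, Fz$dx),
                            dims = c(nfree, nfree))
  b <- numeric(nfree)
  bi <- c(Fr$bi, Fz$bi)
  if (length(bi)) {
    agg <- rowsum(c(Fr$bx, Fz$bx), bi)
    b[as.integer(rownames(agg))] <- agg[, 1]
  }
  if (!is.null(charge_density)) {
    if (!is.matrix(charge_density) ||
        !all(dim(charge_density) == c(n_r, n_z)))
      .stopf("charge_density must be a %d x %d matrix", n_r, n_z)
    vol <- if (axis) {
      v <- rad * h^2; v[rad == 0] <- h^3 / 8; matrix(v, n_r, n_z)
    } else matrix(h^2, n_r, n_z)
    b <- b + charge_density[free] * vol[free] / .const$eps0
  }
  list(A = A, b = b, free = free, fmap = fmap)
}

#' Solve Poisson's equation on a device grid
#'
#' Solves the five-point finite-difference discretisation of Poisson's
#' equation with Dirichlet conditions on the conductor nodes and
#' homogeneous Neumann conditions on open boundaries. The default backend
#' is a sparse symmetric factorisation; `method = "sor"` runs red-black
#' successive over-relaxation instead (useful on small grids and as an
#' independent path).
#'
#' @param grid an `espray_grid` from [build_grid()] or
#'   [parallel_plate_grid()]
#' @param charge_density optional free-charge density per node (C/m^3),
#'   a `n_r x n_z` matrix; default zero (Laplace problem)
#' @param method `"direct"` (sparse factorisation) or `"sor"`
#' @param tol relative-residual tolerance for the iterative method
#' @param max_sweeps iteration cap for `"sor"`
#' @param omega over-relaxation factor for `"sor"`
#' @return an object of class `espray_potential_map`: the grid, the solved
#'   potential (V) on every node (Dirichlet values on conductors), and the
#'   final relative residual of the linear system
#' @examples
#' g <- parallel_plate_grid(10e-3, operating_potential(1e3), spacing = 1e-3)
#' pm <- solve_poisson(g)
#' pm$residual
#' @export
solve_poisson <- function(grid, charge_density = NULL,
                          method = c("direct", "sor"),
                          tol = 1e-8, max_sweeps = 1e5, omega = 1.9) {
  stopifnot(inherits(grid, "espray_grid"))
  method <- match.arg(method)
  sys <- .assemble_poisson(grid, charge_density)
  bscale <- max(sqrt(sum(sys$b^2)), .Machine$double.xmin)
  if (method == "direct") {
    phi_f <- as.numeric(Matrix::solve(Matrix::forceSymmetric(sys$A), sys$b))
  } else {
    phi_f <- .sor_solve(grid, sys, tol = tol, max_sweeps = max_sweeps,
                        omega = omega)
  }
  residual <- sqrt(sum((as.numeric(sys$A %*% phi_f) - sys$b)^2)) / bscale
  values <- matrix(NA_real_, grid$n_r, grid$n_z)
  values[sys$free] <- phi_f
  values[grid$mask == 1L] <- grid$dirichlet[["needle"]]
  values[grid$mask == 2L] <- grid$dirichlet[["plate"]]
  structure(list(grid = grid, values = values, residual = residual,
                 method = method),
            class = "espray_potential_map")
}

# red-black SOR on the same finite-volume stencil
.sor_solve <- function(grid, sys, tol, max_sweeps, omega) {
  n_r <- grid$n_r; n_z <- grid$n_z; h <- grid$spacing
  mask <- grid$mask; free <- sys$free
  axis <- grid$mode == "axisymmetric"
  rad <- abs(grid$r)
  g_vert <- if (axis) { g <- rad; g[rad == 0] <- h / 8; g } else rep(1, n_r)
  g_rad  <- if (axis) rad[-n_r] + h / 2 else rep(1, n_r - 1)

  gE <- matrix(0, n_r, n_z); gE[-n_r, ] <- g_rad          # towards +r
  gW <- matrix(0, n_r, n_z); gW[-1, ]   <- g_rad          # towards -r
  gN <- matrix(0, n_r, n_z); gN[, -n_z] <- rep(g_vert, n_z - 1)
  gS <- matrix(0, n_r, n_z); gS[, -1]   <- rep(g_vert, n_z - 1)
  diagc <- gE + gW + gN + gS

  # conductor potentials and charge terms are already folded into sys$b
  src <- matrix(0, n_r, n_z)
  src[sys$free] <- sys$b

  phi <- matrix(0, n_r, n_z)
  phi[mask == 1L] <- grid$dirichlet[["needle"]]
  phi[mask == 2L] <- grid$dirichlet[["plate"]]

  shift <- function(m, dr, dz) {
    out <- matrix(0, n_r, n_z)
    rs <- seq_len(n_r) + dr; zs <- seq_len(n_z) + dz
    okr <- rs >= 1 & rs <= n_r; okz <- zs >= 1 & zs <= n_z
    out[okr, okz] <- m[rs[okr], zs[okz]]
    out
  }
  parity <- outer(seq_len(n_r), seq_len(n_z), "+") %% 2L
  red <- free & parity == 0L
  black <- free & parity == 1L
  bscale <- max(sqrt(sum(sys$b^2)), .Machine$double.xmin)

  resid <- Inf
  for (sweep in seq_len(max_sweeps)) {
    for (cells in list(red, black)) {
      # conductor neighbours are part of src, so sum free neighbours only
      pf <- phi * free
      nbf <- gE * shift(pf, 1L, 0L) + gW * shift(pf, -1L, 0L) +
             gN * shift(pf, 0L, 1L) + gS * shift(pf, 0L, -1L)
      gs <- (nbf + src) / diagc
      phi[cells] <- (1 - omega) * phi[cells] + omega * gs[cells]
    }
    if (sweep %% 50L == 0L || sweep == max_sweeps) {
      phi_f <- phi[sys$free]
      resid <- sqrt(sum((as.numeric(sys$A %*% phi_f) - sys$b)^2)) / bscale
      if (resid <= tol) return(phi_f)
    }
  }
  cond <- structure(class = c("espray_solver_error", "error", "condition"),
                    list(message = sprintf(
                      "SOR did not reach tol %g in %d sweeps (residual %g)",
                      tol, as.integer(max_sweeps), resid),
                      call = sys.call(-1), residual = resid))
  stop(cond)
}

#' @export
print.espray_potential_map <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("<espray potential map> %d x %d nodes, %s solve\n",
              x$grid$n_r, x$grid$n_z, x$method))
  cat(sprintf("  potential range: %.3f .. %.3f kV; relative residual %.2e\n",
              rng[1] / 1e3, rng[2] / 1e3, x$residual))
  invisible(x)
}
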