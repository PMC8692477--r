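# Shared fixtures: a scaled-down device (short gap, short needle) keeps
# unit-test solves to a few thousand nodes; the full-scale study geometry
# is exercised in the acceptance tests.

small_geometry <- function() {
  device_geometry(gap = 10e-3, needle_protrusion = 5e-3,
                  plate_half_width = 6e-3, domain_half_width = 6e-3,
                  domain_height_above = 3e-3)
}

small_field <- function(kv = 15, spacing = 100e-6,
                        mode = "axisymmetric") {
  grid <- build_grid(small_geometry(), operating_potential(kv * 1e3),
                     spacing = spacing, mode = mode)
  compute_field(solve_poisson(grid))
}

# dense reference solve of the identical finite-volume stencil, written
# with explicit loops so it shares nothing with the package assembly
dense_poisson_oracle <- function(grid) {
  h <- grid$spacing; n_r <- grid$n_r; n_z <- grid$n_z
  mask <- grid$mask
  axis <- grid$mode == "axisymmetric"
  rad <- abs(grid$r)
  gv <- function(i) if (!axis) 1 else if (rad[i] == 0) h / 8 else rad[i]
  gr <- function(i) if (!axis) 1 else (rad[i] + rad[i + 1]) / 2  # r_{i+1/2}
  phi_of <- function(m) grid$dirichlet[[c("needle", "plate")[m]]]
  free_idx <- which(mask == 0L)
  n <- length(free_idx)
  pos <- function(i, k) (k - 1L) * n_r + i
  fnum <- integer(n_r * n_z); fnum[free_idx] <- seq_len(n)
  A <- matrix(0, n, n); b <- numeric(n)
  for (k in seq_len(n_z)) for (i in seq_len(n_r)) {
    if (mask[i, k] != 0L) next
    row <- fnum[pos(i, k)]
    nb <- list(c(i + 1L, k, if (i < n_r) gr(i) else NA),
               c(i - 1L, k, if (i > 1L) gr(i - 1L) else NA),
               c(i, k + 1L, if (k < n_z) gv(i) else NA),
               c(i, k - 1L, if (k > 1L) gv(i) else NA))
    for (e in nb) {
      if (is.na(e[3])) next
      g <- e[3]
      A[row, row] <- A[row, row] + g
      m <- mask[e[1], e[2]]
      if (m == 0L) A[row, fnum[pos(e[1], e[2])]] <-
          A[row, fnum[pos(e[1], e[2])]] - g
      else b[row] <- b[row] + g * phi_of(m)
    }
  }
  phi <- matrix(NA_real_, n_r, n_z)
  phi[free_idx] <- solve(A, b)
  phi[mask == 1L] <- grid$dirichlet[["needle"]]
  phi[mask == 2L] <- grid$dirichlet[["plate"]]
  phi
}
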