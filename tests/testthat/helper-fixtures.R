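# shared fixtures and independent oracles used across the suite

# render an isolated Gaussian spot at continuous (x_um, z_um) on an
# nz x nx grid -- independent of the package's render_spots()
spot_image <- function(nz, nx, x_um, z_um, sigma_um, pixel_um = 1,
                       amplitude = 1) {
  zz <- ((seq_len(nz) - 0.5) * pixel_um - z_um)
  xx <- ((seq_len(nx) - 0.5) * pixel_um - x_um)
  amplitude * outer(exp(-zz^2 / (2 * sigma_um^2)),
                    exp(-xx^2 / (2 * sigma_um^2)))
}

# brute-force polyline rasterization oracle: same sampling definition as
# rasterize_tracks (mid-point samples at grid resolution) but written as an
# explicit per-point loop with no shared code
rasterize_oracle_support <- function(track, grid_um, extent_um) {
  nx <- ceiling(extent_um[1] / grid_um)
  nz <- ceiling(extent_um[2] / grid_um)
  hit <- matrix(FALSE, nz, nx)
  for (k in seq_len(nrow(track) - 1)) {
    x0 <- track$x_um[k]; z0 <- track$z_um[k]
    x1 <- track$x_um[k + 1]; z1 <- track$z_um[k + 1]
    n_sub <- max(1, ceiling(sqrt((x1 - x0)^2 + (z1 - z0)^2) / grid_um))
    for (q in seq_len(n_sub)) {
      f <- (q - 0.5) / n_sub
      ix <- min(max(ceiling((x0 + f * (x1 - x0)) / grid_um), 1), nx)
      iz <- min(max(ceiling((z0 + f * (z1 - z0)) / grid_um), 1), nz)
      hit[iz, ix] <- TRUE
    }
  }
  hit
}

# distance from points to a vessel segment (perpendicular, clamped to ends)
point_segment_dist <- function(px, pz, seg) {
  dx <- seg$x1_um - seg$x0_um; dz <- seg$z1_um - seg$z0_um
  L2 <- dx^2 + dz^2
  t <- pmin(pmax(((px - seg$x0_um) * dx + (pz - seg$z0_um) * dz) / L2, 0), 1)
  sqrt((px - (seg$x0_um + t * dx))^2 + (pz - (seg$z0_um + t * dz))^2)
}

# a small deterministic phantom reused by several tests
small_phantom <- function(seed = 21)
  generate_phantom(n_per_level = c(5L, 5L, 5L, 5L),
                   extent_um = c(1500, 1500), seed = seed)
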