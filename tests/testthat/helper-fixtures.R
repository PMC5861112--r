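# Fixtures built in code: no data files.

# Partial-volume voxelized uniform sphere as an initial-pressure map:
# the standard analytic test source (N-wave oracle). Occupancy of boundary
# voxels is supersampled ss^3 times.
sphere_p0_map <- function(a = 1, depth = 10.05, h = 0.025, pad = 0.15, ss = 4L) {
  nx <- as.integer(ceiling((2 * a + 2 * pad) / h))
  nz <- as.integer(ceiling((depth + a + pad) / h))
  x <- (seq_len(nx) - 0.5) * h - nx * h / 2
  z <- (seq_len(nz) - 0.5) * h
  off <- (seq_len(ss) - (ss + 1) / 2) / ss * h
  occ <- array(0, c(nx, nx, nz))
  for (ox in off) for (oy in off) for (oz in off) {
    r2 <- outer(outer((x + ox)^2, (x + oy)^2, `+`), (z + oz - depth)^2, `+`)
    occ <- occ + (r2 <= a^2)
  }
  structure(list(p0 = occ / ss^3, voxel_mm = h,
                 labels = array(0L, dim(occ))),
            class = "initial_pressure_map")
}

# Small uniform slab phantom
uniform_phantom <- function(d = c(20L, 20L, 24L), voxel_mm = 0.5,
                            mu_a = 0.3, mus_prime = 10, g = 0.9,
                            labels = array(0L, dim = d)) {
  mu_s <- if (g < 1) mus_prime / (1 - g) else 0
  optical_phantom(array(mu_a, d), array(mu_s, d), g, labels, voxel_mm)
}

# Single-voxel point source map at lateral centre, given depth; the grid
# is deliberately small laterally (sources only exist near the axis).
point_p0_map <- function(depth = 15, h = 0.1, nx = 21L, nz = NULL, value = 1) {
  if (is.null(nz)) nz <- as.integer(ceiling(depth / h) + 10L)
  p0 <- array(0, c(nx, nx, nz))
  iz <- as.integer(round(depth / h + 0.5))
  ic <- (nx + 1L) %/% 2L
  p0[ic, ic, iz] <- value
  structure(list(p0 = p0, voxel_mm = h, labels = array(0L, dim(p0))),
            class = "initial_pressure_map")
}

# Clean linear-array RF for a point target (round-trip fixture)
point_target_rf <- function(depth = 15, n_elements = 64L, pitch_mm = 0.3,
                            dt_us = 0.05, v_s = 1500) {
  m <- point_p0_map(depth)
  det <- detector_spec("linear_array", element_count = n_elements,
                       pitch_mm = pitch_mm, dt_us = dt_us)
  pa_trace_superposition(m, det, v_s)
}

# true centre coordinates of the point source in point_p0_map
point_p0_center <- function(depth = 15, h = 0.1, nx = 21L) {
  iz <- as.integer(round(depth / h + 0.5))
  ic <- (nx + 1L) %/% 2L
  c(x = (ic - 0.5) * h - nx * h / 2, z = (iz - 0.5) * h)
}
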