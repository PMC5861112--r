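test_that("initial pressure is Gamma times energy density", {
  ph <- uniform_phantom(d = c(6L, 6L, 6L))
  em <- run_mc(ph, beam_spec(0.2), 2e3, seed = 4)
  expect_error(initial_pressure(em, ph), "apply_temperature")
  m <- thermo_model()
  ph2 <- apply_temperature(ph, c(medium = 20, target = 37), m)
  p <- initial_pressure(em, ph2)
  expect_equal(p$p0, m$gamma_ref * em$values / 0.5^3)

  # uniform energy, uniform Gamma -> uniform p0 = gamma e / V
  em$values[] <- 3e-6
  expect_equal(unique(as.numeric(initial_pressure(em, ph2)$p0)),
               m$gamma_ref * 3e-6 / 0.5^3)

  # zero Gamma -> zero pressure
  ph0 <- ph2; ph0$gamma[] <- 0
  expect_true(all(initial_pressure(em, ph0)$p0 == 0))

  # halving the medium Gamma halves p0 outside the target only
  rec <- phantom_recipe(target_depth = 8, slab_mm = c(16, 16, 16))
  pht <- apply_temperature(build_slab_rod_phantom(rec),
                           c(medium = 20, target = 37), m)
  emt <- run_mc(pht, beam_spec(1), 5e3, seed = 6)
  p1 <- initial_pressure(emt, pht)
  ph_half <- pht; ph_half$gamma[ph_half$labels == 0L] <-
    ph_half$gamma[ph_half$labels == 0L] / 2
  p2 <- initial_pressure(emt, ph_half)
  med <- pht$labels == 0L
  expect_equal(p2$p0[med], p1$p0[med] / 2)
  expect_identical(p2$p0[!med], p1$p0[!med])
})

test_that("shell decomposition partitions energy and is local", {
  rec <- phantom_recipe(target_depth = 10, slab_mm = c(24, 24, 16))
  m <- thermo_model()
  ph <- apply_temperature(build_slab_rod_phantom(rec),
                          c(medium = 20, target = 37), m)
  em <- run_mc(ph, beam_spec(1), 2e4, seed = 8)
  det <- detector_spec("point", dt_us = 0.4)
  sh <- shell_decompose(em, ph, det, 1500)
  # conservation over the partition
  expect_equal(sum(sh$e_shell_background) + sum(sh$e_shell_target),
               sum(em$values), tolerance = 1e-12)
  # background + target equals the per-shell total energy
  expect_true(all(sh$e_shell_target[sh$e_shell_target > 0] > 0))

  # no target -> target shells identically zero
  rec0 <- phantom_recipe(rod_thickness = 0, slab_mm = c(24, 24, 16))
  ph0 <- apply_temperature(build_slab_rod_phantom(rec0),
                           c(medium = 20, target = 37), m)
  em0 <- run_mc(ph0, beam_spec(1), 5e3, seed = 8)
  sh0 <- shell_decompose(em0, ph0, det, 1500)
  expect_true(all(sh0$e_shell_target == 0))

  # single nonzero voxel lands in exactly one shell at round(r / dr)
  emx <- em0
  emx$values[] <- 0
  emx$values[12, 12, 14] <- 1
  co <- phantom_coords(ph0)
  r <- sqrt(co$x[12]^2 + co$y[12]^2 + co$z[14]^2)
  shx <- shell_decompose(emx, ph0, det, 1500)
  k <- which(shx$e_shell_background > 0)
  expect_length(k, 1L)
  expect_equal(k - 1L, round(r / shx$dr_mm))
})

test_that("shell traces are exactly linear in the regional Gammas", {
  rec <- phantom_recipe(target_depth = 10, slab_mm = c(24, 24, 16))
  m <- thermo_model()
  ph <- apply_temperature(build_slab_rod_phantom(rec),
                          c(medium = 20, target = 37), m)
  em <- run_mc(ph, beam_spec(1), 1e4, seed = 8)
  sh <- shell_decompose(em, ph, detector_spec("point", dt_us = 0.4), 1500)
  tr1 <- pa_trace_shell(sh, 1, 1)
  trk <- pa_trace_shell(sh, 2.5, 1)
  expect_equal(trk$pa_noise$values, 2.5 * tr1$pa_noise$values)
  expect_identical(trk$pa_signal$values, tr1$pa_signal$values)
  tr0 <- pa_trace_shell(sh, 0, 1)
  expect_true(all(tr0$pa_noise$values == 0))
  # gamma-only cooling 35 -> 5 degC scales the noise by the same factor at
  # every time sample
  f35 <- grueneisen_scale(35, m); f5 <- grueneisen_scale(5, m)
  a <- pa_trace_shell(sh, m$gamma_ref * f35, 1)$pa_noise$values
  b <- pa_trace_shell(sh, m$gamma_ref * f5, 1)$pa_noise$values
  nz <- a != 0
  expect_equal(a[nz] / b[nz], rep(1.225 / 0.775, sum(nz)))
})

test_that("N-wave closed form has the textbook shape", {
  v <- 1500
  r <- 10; a <- 1; p0 <- 2
  t0 <- r / 1.5
  expect_identical(nwave_analytic(p0, a, r, v, t0), 0)       # zero crossing
  expect_equal(nwave_analytic(p0, a, r, v, (r - a) / 1.5), p0 * a / (2 * r))
  # antisymmetric about t = r / v
  dt <- seq(-0.6, 0.6, by = 0.05)
  expect_equal(nwave_analytic(p0, a, r, v, t0 + dt),
               -nwave_analytic(p0, a, r, v, t0 - dt))
  expect_identical(nwave_analytic(p0, a, r, v, (r + 2 * a) / 1.5), 0)
})

test_that("superposition is linear and times arrivals like the shell model", {
  # dt resolves the single-voxel N-wave (about 0.15 us at 0.1 mm voxels)
  m <- point_p0_map(depth = 12)
  det <- detector_spec("point", dt_us = 0.04)
  tr <- pa_trace_superposition(m, det, 1500)
  m2 <- m; m2$p0 <- 2 * m$p0
  tr2 <- pa_trace_superposition(m2, det, 1500)
  expect_equal(tr2$values, 2 * tr$values)

  m0 <- m; m0$p0[] <- 0
  expect_true(all(pa_trace_superposition(m0, det, 1500)$values == 0))

  # arrival bin agreement between the two forward models
  ctr <- point_p0_center(12)
  r <- sqrt(ctr["x"]^2 + ctr["z"]^2)
  k_sup <- which.max(abs(tr$values))
  expect_lt(abs(tr$times[k_sup] - r / 1.5), 0.5) # within the bipolar width
  ph <- uniform_phantom(d = dim(m$p0), voxel_mm = 0.1)
  em <- run_mc(ph, beam_spec(0.1), 10, seed = 1)
  em$values <- m$p0
  sh <- shell_decompose(em, ph, det, 1500, dt_us = 0.4)
  k_shell <- which.max(sh$e_shell_background)
  expect_lt(abs(sh$times[k_shell] - r / 1.5), 0.4)
})

test_that("aperture detectors average and short records warn", {
  m <- point_p0_map(depth = 8)
  det_pt <- detector_spec("point", dt_us = 0.04)
  det_ap <- detector_spec("square_aperture", dt_us = 0.04)
  trp <- pa_trace_superposition(m, det_pt, 1500)
  tra <- pa_trace_superposition(m, det_ap, 1500)
  expect_equal(which.max(abs(tra$values)), which.max(abs(trp$values)),
               tolerance = 2)
  # aperture spreads arrivals: peak no larger than the point trace
  expect_lte(max(abs(tra$values)), max(abs(trp$values)) * 1.01)
  expect_warning(pa_trace_superposition(m, det_pt, 1500, record_length = 20),
                 "truncated")
})
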