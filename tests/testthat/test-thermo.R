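test_that("Grueneisen scaling follows the linear anchor convention", {
  m <- thermo_model()
  expect_identical(grueneisen_scale(m$t_ref, m), 1)
  expect_equal(grueneisen_scale(m$t_ref + 1, m), 1.015)
  # 35 vs 5 degC around the 20 degC anchor
  expect_equal(grueneisen_scale(35, m) / grueneisen_scale(5, m), 1.225 / 0.775)
  expect_equal(grueneisen_scale(35, m) / grueneisen_scale(5, m), 1.5806,
               tolerance = 1e-4)
})

test_that("compounding variant multiplies per degree", {
  m <- thermo_model(compounding = TRUE)
  expect_identical(grueneisen_scale(m$t_ref, m), 1)
  expect_equal(grueneisen_scale(25, m), 1.015^5)
  expect_equal(grueneisen_scale(5, m), 1.015^-15)
})

test_that("temperature range is enforced", {
  m <- thermo_model()
  expect_error(grueneisen_scale(-1, m), "range")
  expect_error(grueneisen_scale(46, m), "range")
  expect_error(reduced_scattering_at(50, 10, m), "range")
  expect_error(speed_of_sound_at(-0.1, m), "range")
})

test_that("Grueneisen from properties matches beta v^2 / c_p", {
  water20 <- medium_properties(beta = 2.07e-4, v_s = 1482, c_p = 4182)
  expect_equal(grueneisen_from_properties(water20), 2.07e-4 * 1482^2 / 4182)
  expect_equal(grueneisen_from_properties(water20), 0.1087, tolerance = 1e-3)
  expect_identical(grueneisen_from_properties(
    medium_properties(beta = 0, v_s = 1500, c_p = 4000)), 0)
})

test_that("Grueneisen is linear in beta, 1/c_p and quadratic in v_s", {
  set.seed(11)
  for (i in 1:20) {
    beta <- runif(1, 1e-5, 1e-3); v <- runif(1, 1000, 2000)
    cp <- runif(1, 1000, 5000); k <- runif(1, 0.5, 3)
    g0 <- grueneisen_from_properties(medium_properties(beta, v, cp))
    expect_equal(grueneisen_from_properties(medium_properties(k * beta, v, cp)),
                 k * g0)
    expect_equal(grueneisen_from_properties(medium_properties(beta, v, k * cp)),
                 g0 / k)
    expect_equal(grueneisen_from_properties(medium_properties(beta, k * v, cp)),
                 k^2 * g0)
  }
})

test_that("scaling laws are strictly increasing in temperature", {
  for (m in list(thermo_model(), thermo_model(compounding = TRUE),
                 thermo_model(rate_gamma = 0.02, rate_mus = 0.01))) {
    T <- seq(0, 45, by = 0.5)
    expect_true(all(diff(grueneisen_scale(T, m)) > 0))
    expect_true(all(diff(reduced_scattering_at(T, 10, m)) > 0))
    # sign of the analytic SNR prediction: colder medium, higher SNR
    expect_true(all(10 * log10(grueneisen_scale(T[-1], m) /
                               grueneisen_scale(T[-length(T)], m)) > 0))
  }
})

test_that("reduced scattering scales around the reference", {
  m <- thermo_model()
  expect_equal(reduced_scattering_at(m$t_ref, 10, m), 10)
  expect_equal(reduced_scattering_at(m$t_ref + 1, 10, m), 10.04)
  expect_equal(reduced_scattering_at(5, 10, m), 9.4)
  # a rate strong enough to zero mus' inside the range is rejected
  m2 <- thermo_model(rate_mus = 0.05)
  expect_error(reduced_scattering_at(0, 10, m2), "non-positive")
})

test_that("speed of sound modes behave", {
  mc <- thermo_model(vs_model = "constant", vs_value = 1540)
  expect_equal(speed_of_sound_at(c(5, 20, 35), mc), rep(1540, 3))
  mw <- thermo_model(vs_model = "water_polynomial")
  v20 <- speed_of_sound_at(20, mw)
  expect_gt(v20, 1480); expect_lt(v20, 1485)
  expect_true(all(diff(speed_of_sound_at(seq(0, 45, 0.25), mw)) > 0))
})

test_that("apply_temperature freezes and scales per scenario", {
  rec <- phantom_recipe(target_depth = 10, slab_mm = c(16, 16, 16))
  ph <- build_slab_rod_phantom(rec)
  m <- thermo_model()
  ref <- apply_temperature(ph, c(medium = 20, target = 20), m, "both")
  expect_equal(unique(as.numeric(ref$gamma)), m$gamma_ref)
  expect_identical(ref$mu_s, ph$mu_s)

  cold <- apply_temperature(ph, c(medium = 5, target = 37), m, "gamma_only")
  med <- cold$labels == 0L; tar <- cold$labels == 1L
  expect_equal(unique(as.numeric(cold$gamma[med])), m$gamma_ref * 0.775)
  expect_equal(unique(as.numeric(cold$gamma[tar])),
               m$gamma_ref * grueneisen_scale(37, m))
  expect_identical(cold$mu_s, ph$mu_s)  # scattering frozen

  mus <- apply_temperature(ph, c(medium = 5, target = 37), m, "mus_only")
  expect_equal(unique(as.numeric(mus$gamma[med])), m$gamma_ref) # Gamma frozen
  expect_equal(unique(as.numeric(mus$mu_s[med])),
               unique(as.numeric(ph$mu_s[med])) * (1 + 0.004 * (5 - 20)))
  expect_identical(mus$mu_s[tar], ph$mu_s[tar])

  # the target state is identical across a medium-temperature sweep
  g37 <- lapply(c(5, 20, 35), function(T)
    apply_temperature(ph, c(medium = T, target = 37), m, "both")$gamma[tar])
  expect_identical(g37[[1]], g37[[2]])
  expect_identical(g37[[1]], g37[[3]])

  expect_error(apply_temperature(ph, c(medium = 5), m), "named")
  expect_error(apply_temperature(ph, c(medium = 50, target = 37), m), "range")
})
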