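test_that("snr_db follows the decibel definition with absolute values", {
  expect_equal(snr_db(3, 3), 0)
  expect_equal(snr_db(10, 1), 10)
  expect_equal(snr_db(-3, 3), 0)   # signs ignored
  expect_equal(snr_db(1, -10), -10)
  expect_identical(snr_db(1, 0), Inf)
})

test_that("trace amplitudes are gated around the arrival time", {
  times <- seq(0.1, 30, by = 0.1)
  v <- numeric(length(times))
  v[100] <- -5; v[102] <- 3   # arrival near sample 100 (t = 10 us)
  tr <- pa_trace(times, v, "true")
  # depth 15 mm at 1500 m/s arrives at t = 10 us
  expect_equal(trace_amplitude_at(tr, 15, 1500), -5)
  expect_equal(trace_amplitude_at(tr, 15, 1500, gate = 0L), -5)
  expect_error(trace_amplitude_at(tr, 100, 1500), "outside")
})

test_that("signal is the difference between target and target-free traces", {
  times <- seq(0.1, 20, by = 0.1)
  noise <- sin(times)
  true_tr <- pa_trace(times, noise + ifelse(abs(times - 10) < 0.2, 2, 0), "true")
  noise_tr <- pa_trace(times, noise, "noise")
  sp <- signal_noise_split(true_tr, noise_tr, 15, 1500)
  # the signal is gated on the difference trace, so it recovers the
  # injected target bump exactly
  expect_equal(sp$pa_signal, 2)
  # identical traces: no target contribution
  sp0 <- signal_noise_split(noise_tr, noise_tr, 15, 1500)
  expect_identical(sp0$pa_signal, 0)
  # zero noise trace: signal equals the measured amplitude
  z <- pa_trace(times, numeric(length(times)), "noise")
  spz <- signal_noise_split(true_tr, z, 15, 1500)
  expect_equal(spz$pa_signal, spz$pa_true)
})

test_that("signal amplitude is invariant to the medium Gamma under shared fluence", {
  # superposition route: the target-free trace is built from the same
  # realization with the target sources zeroed, so PA_true - PA_noise is
  # exactly the target contribution, which does not depend on the medium
  # Gamma.
  rec <- phantom_recipe(target_depth = 10, slab_mm = c(24, 24, 16))
  m <- thermo_model()
  base <- build_slab_rod_phantom(rec)
  em <- run_mc(apply_temperature(base, c(medium = 20, target = 37), m),
               beam_spec(1), 2e4, seed = 13)
  det <- detector_spec("point", dt_us = 0.1)
  sig <- sapply(c(5, 20, 35), function(T) {
    ph <- apply_temperature(base, c(medium = T, target = 37), m, "gamma_only")
    p0 <- initial_pressure(em, ph)
    p0_noise <- p0; p0_noise$p0[ph$labels == 1L] <- 0
    tr_true <- pa_trace_superposition(p0, det, 1500)
    tr_noise <- pa_trace_superposition(p0_noise, det, 1500)
    signal_noise_split(tr_true, tr_noise, 10, 1500)$pa_signal
  })
  expect_equal(sig[1], sig[2], tolerance = 1e-12)
  expect_equal(sig[1], sig[3], tolerance = 1e-12)
})

test_that("analytic SNR difference matches the Gamma ratio", {
  m <- thermo_model()
  expect_equal(delta_snr_analytic(20, 20, m), 0)
  expect_equal(delta_snr_analytic(35, 5, m), 10 * log10(1.225 / 0.775))
  expect_equal(delta_snr_analytic(35, 5, m), 1.988, tolerance = 1e-3)
  mc <- thermo_model(compounding = TRUE)
  expect_equal(delta_snr_analytic(35, 5, mc), 10 * log10(1.015^30))
  expect_equal(delta_snr_analytic(35, 5, mc), 1.940, tolerance = 1e-3)
  # antisymmetry
  expect_equal(delta_snr_analytic(5, 35, m), -delta_snr_analytic(35, 5, m))
})

mk_image <- function(bg, peak = NULL) {
  nx <- nrow(bg); nz <- ncol(bg)
  img <- structure(list(pixels = bg, x = seq_len(nx) * 0.1,
                        z = seq_len(nz) * 0.1),
                   class = "reconstructed_image")
  if (!is.null(peak)) img$pixels[nx %/% 2, nz %/% 2] <- peak
  img
}

test_that("image SNR is the squared peak over the background variance", {
  set.seed(7)
  bg <- matrix(rnorm(120 * 120, sd = 0.1), 120)
  img <- mk_image(bg, peak = 1)
  s <- image_snr(img)
  expect_equal(s, 20, tolerance = 0.4)   # 10 log10(1 / 0.01)
  # scale invariance
  img2 <- img; img2$pixels <- img$pixels * 8.5
  expect_equal(image_snr(img2), s)
  # doubling the background std costs ~6 dB (variance quadruples): same
  # draws scaled exactly
  img4 <- mk_image(2 * bg, peak = 1)
  expect_equal(image_snr(img) - image_snr(img4), 10 * log10(4),
               tolerance = 0.02)
})

test_that("image SNR background region and sentinels behave", {
  set.seed(8)
  bg <- matrix(rnorm(80 * 80, sd = 0.05), 80)
  img <- mk_image(bg, peak = 2)
  # explicit background mask overrides the default
  mask <- matrix(TRUE, 80, 80); mask[20:60, 20:60] <- FALSE
  s <- image_snr(img, background = mask)
  expect_true(is.finite(s))
  expect_error(image_snr(img, background = matrix(TRUE, 80, 80)),
               "exclude the detected peak")
  # zero background variance -> infinite sentinel
  flat <- mk_image(matrix(0, 90, 90), peak = 1)
  expect_identical(image_snr(flat), Inf)
  # ROI-restricted peak search finds the target, not the brighter clutter
  imgr <- mk_image(bg, peak = NULL)
  imgr$pixels[10, 10] <- 5      # clutter
  imgr$pixels[40, 40] <- 1      # target
  roi <- matrix(FALSE, 80, 80); roi[35:45, 35:45] <- TRUE
  expect_lt(image_snr(imgr, roi = roi), image_snr(imgr))
})
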