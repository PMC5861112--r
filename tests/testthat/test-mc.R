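test_that("Henyey-Greenstein sampling has the right limits and mean", {
  expect_identical(sample_hg_cosine(0, 0.5), 0)
  expect_equal(sample_hg_cosine(0, c(0, 0.25, 0.75)), c(-1, -0.5, 0.5))
  set.seed(21)
  for (g in c(0.3, 0.7)) {
    u <- runif(2e5)
    cs <- sample_hg_cosine(g, u)
    expect_lt(abs(mean(cs) - g), 3 * sd(cs) / sqrt(length(cs)))
    expect_true(all(cs >= -1 & cs <= 1))
  }
  # g -> 1: all mass at cos = 1
  expect_true(all(sample_hg_cosine(1 - 1e-9, seq(0.01, 0.99, 0.01)) > 0.999))
})

test_that("Beer-Lambert oracle evaluates the closed form", {
  expect_identical(beer_lambert_oracle(0.3, 0), 1)
  expect_equal(beer_lambert_oracle(0.3, 1), exp(-0.3))
  expect_equal(beer_lambert_oracle(30, 0.1), exp(-3))
})

test_that("energy bookkeeping is exact on every kind of run", {
  bm <- beam_spec(0.4)
  runs <- list(
    scattering = uniform_phantom(),
    absorbing = uniform_phantom(mu_a = 2, mus_prime = 1e-9, g = 0),
    transparent = uniform_phantom(mu_a = 0, mus_prime = 5, g = 0.5))
  for (nm in names(runs)) {
    em <- run_mc(runs[[nm]], bm, 2e4, seed = 5)
    cons <- sum(em$values) + em$escaped + em$rr_lost - em$rr_gained
    expect_lt(abs(cons - 1), 1e-9)
    expect_equal(sum(em$values) + em$escaped_fraction, 1, tolerance = 1e-9)
  }
  em0 <- run_mc(runs$transparent, bm, 2e4, seed = 5)
  expect_identical(sum(em0$values), 0)       # nothing absorbs
  expect_equal(em0$escaped_fraction, 1, tolerance = 1e-12)
})

test_that("fixed seed reproduces the map bit for bit and seeds differ", {
  ph <- uniform_phantom(d = c(12L, 12L, 12L))
  bm <- beam_spec(0.4)
  a <- run_mc(ph, bm, 5e3, seed = 17)
  b <- run_mc(ph, bm, 5e3, seed = 17)
  c <- run_mc(ph, bm, 5e3, seed = 18)
  expect_identical(a$values, b$values)
  expect_identical(a$escaped, b$escaped)
  expect_false(identical(a$values, c$values))
})

test_that("Monte-Carlo standard error scales as 1 / sqrt(n_photons)", {
  ph <- uniform_phantom(d = c(16L, 16L, 16L))
  bm <- beam_spec(0.4)
  se_tot <- function(n) {
    em <- run_mc(ph, bm, n, seed = 30, n_batches = 25L)
    tot <- colSums(em$batch_region) * 25      # per-batch estimates of total
    sd(tot) / sqrt(25)
  }
  r <- se_tot(4e3) / se_tot(6.4e4)
  expect_gt(r, 4 * 0.55)   # expected ratio 4
  expect_lt(r, 4 * 1.8)
})

test_that("roulette is unbiased: deposited total invariant to threshold", {
  ph <- uniform_phantom(d = c(24L, 24L, 24L), mu_a = 1, mus_prime = 5, g = 0.8)
  bm <- beam_spec(0.4)
  a <- run_mc(ph, bm, 4e4, seed = 9, rr_threshold = 1e-4)
  b <- run_mc(ph, bm, 4e4, seed = 10, rr_threshold = 1e-2)
  se <- function(em) {
    tot <- colSums(em$batch_region) * em$n_batches
    sd(tot) / sqrt(em$n_batches)
  }
  z <- abs(sum(a$values) - sum(b$values)) / sqrt(se(a)^2 + se(b)^2)
  expect_lt(z, 4)
})

test_that("non-scattering pencil beam reproduces Beer-Lambert decay", {
  d <- c(21L, 21L, 45L)
  ph <- optical_phantom(array(1, d), array(0, d), 0, array(0L, d), 0.5)
  em <- run_mc(ph, beam_spec(0), 1e5, seed = 5)  # pencil on the centre voxel
  F <- fluence_from_energy(em, ph)
  z <- (seq_len(d[3]) - 0.5) * 0.05
  Fax <- F[11, 11, ] * 0.05^2   # fluence x voxel area = transmitted fraction
  sel <- z <= 2
  expect_lt(max(abs(Fax[sel] / exp(-z[sel]) - 1)), 0.02)
})

test_that("deep fluence decay matches diffusion theory in a wide slab", {
  d <- c(80L, 80L, 60L)
  g <- 0.9
  ph <- optical_phantom(array(0.3, d), array(10 / (1 - g), d), g,
                        array(0L, d), 1)
  em <- run_mc(ph, beam_spec(4), 2e5, seed = 11)
  F <- fluence_from_energy(em, ph)
  z <- (seq_len(d[3]) - 0.5) * 0.1
  Fax <- apply(F[38:43, 38:43, ], 3, mean)
  sel <- z >= 1.5 & z <= 4
  fit <- stats::lm(log(Fax[sel]) ~ z[sel])
  mu_eff <- sqrt(3 * 0.3 * (0.3 + 10))
  expect_lt(abs(-coef(fit)[2] / mu_eff - 1), 0.1)
})

test_that("fluence / energy conversions round trip", {
  ph <- uniform_phantom(d = c(10L, 10L, 10L))
  em <- run_mc(ph, beam_spec(0.3), 5e3, seed = 2)
  F <- fluence_from_energy(em, ph)
  expect_equal(energy_from_fluence(F, ph), em$values, tolerance = 1e-12)
  # uniform E, uniform mu_a -> uniform F
  em$values[] <- 2e-6
  expect_equal(diff(range(fluence_from_energy(em, ph))), 0)
  # mu_a = 0 voxels undefined
  ph0 <- uniform_phantom(d = c(4L, 4L, 4L), mu_a = 0)
  em0 <- run_mc(ph0, beam_spec(0.1), 100, seed = 1)
  expect_true(all(is.na(fluence_from_energy(em0, ph0))))
})

test_that("invalid inputs are rejected", {
  ph <- uniform_phantom(d = c(4L, 4L, 4L))
  expect_error(run_mc(ph, beam_spec(0.1), 0, seed = 1), "n_photons")
  expect_error(run_mc(ph, beam_spec(0.1), 10, seed = 1.5), "seed")
  expect_error(fluence_from_energy(
    run_mc(ph, beam_spec(0.1), 10, seed = 1),
    uniform_phantom(d = c(5L, 5L, 5L))), "mismatch")
})
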