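# Monte-Carlo light transport: R-facing wrapper around the compiled
# photon random walk, plus the small analytic oracles used to validate it.

#' Run the Monte-Carlo light transport
#'
#' Simulates weighted photon random walks through the phantom: scattering
#' free paths drawn from the local mu_s, Henyey-Greenstein direction
#' sampling with the local anisotropy, continuous absorption weighting
#' along every traversed voxel, Russian roulette termination below a weight
#' threshold, and matched boundaries (photons leaving the grid are tallied
#' as escaped). The result is the per-voxel deposited energy per unit
#' launched energy.
#'
#' Bookkeeping is exact: `sum(values) + escaped + rr_lost - rr_gained`
#' equals the launched energy to floating-point accuracy, where the last
#' two terms account for Russian-roulette kills and survival boosts.
#'
#' @param phantom An [optical_phantom()].
#' @param beam A [beam_spec()].
#' @param n_photons Number of photons (>= 1).
#' @param seed Integer seed. Photon `i` draws from a counter-based
#'   substream keyed by `(seed, i)`, so a fixed seed gives bit-identical
#'   maps on any platform, and two runs with equal seeds use identical
#'   randomness photon by photon (common random numbers for paired
#'   comparisons).
#' @param n_batches Photon batches for standard-error estimation (per-batch
#'   background/target deposition totals are always returned).
#' @param batch_maps If `TRUE`, also return per-batch deposition maps
#'   (voxels x batches matrix) for batch-wise error estimates of derived
#'   quantities.
#' @param rr_threshold,rr_survive Russian-roulette weight threshold and
#'   survival probability.
#' @return An object of class `absorbed_energy_map`: a list with the 3-D
#'   array `values` (deposited energy fraction per voxel), `escaped_fraction`
#'   (escape plus net roulette loss), the raw tallies, per-batch region
#'   totals, and provenance (`n_photons`, `seed`).
#' @export
run_mc <- function(phantom, beam, n_photons, seed,
                   n_batches = 20L, batch_maps = FALSE,
                   rr_threshold = 1e-4, rr_survive = 0.1) {
  stopifnot(inherits(phantom, "optical_phantom"), inherits(beam, "beam_spec"))
  if (!is.numeric(n_photons) || n_photons < 1) stop("`n_photons` must be >= 1")
  if (!is.numeric(seed) || !is.finite(seed) || seed != round(seed))
    stop("`seed` must be a finite integer")
  n_photons <- as.integer(n_photons)
  n_batches <- max(1L, min(as.integer(n_batches), n_photons))

  d <- dim(phantom$mu_a)
  h_cm <- phantom$voxel_mm / 10
  # beam centre in grid coordinates (origin at the corner of the grid)
  cx <- d[1] * h_cm / 2 + beam$center_mm[1] / 10
  cy <- d[2] * h_cm / 2 + beam$center_mm[2] / 10

  res <- .mc_transport_cpp(as.numeric(phantom$mu_a), as.numeric(phantom$mu_s),
                           as.numeric(phantom$g), as.integer(phantom$labels),
                           as.integer(d), h_cm,
                           beam$diameter_cm / 2, cx, cy,
                           n_photons, n_batches, as.numeric(seed),
                           rr_threshold, rr_survive, isTRUE(batch_maps))

  values <- array(res$values / n_photons, dim = d)
  out <- structure(list(
    values = values,
    escaped_fraction = (res$escaped + res$rr_lost - res$rr_gained) / n_photons,
    escaped = res$escaped / n_photons,
    rr_lost = res$rr_lost / n_photons,
    rr_gained = res$rr_gained / n_photons,
    batch_region = res$batch_region / n_photons,
    photons_launched = n_photons,
    n_batches = n_batches,
    seed = as.integer(seed),
    voxel_mm = phantom$voxel_mm), class = "absorbed_energy_map")
  if (isTRUE(batch_maps)) out$batch_maps <- res$batch_maps / n_photons
  out
}

# get/set .Random.seed without touching it when absent
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(x) {
  if (is.null(x)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", x, envir = globalenv())
}

#' @export
print.absorbed_energy_map <- function(x, ...) {
  cat(sprintf("absorbed_energy_map: %s voxels, %g photons (seed %d)\n",
              paste(dim(x$values), collapse = " x "), x$photons_launched, x$seed))
  cat(sprintf("  deposited %.4f, escaped %.4f (incl. roulette net %.2e)\n",
              sum(x$values), x$escaped_fraction, x$rr_lost - x$rr_gained))
  invisible(x)
}

#' Sample the Henyey-Greenstein scattering cosine
#'
#' Analytic inverse-CDF sampling of the Henyey-Greenstein phase function:
#' given anisotropy `g` and a uniform deviate `u`, returns the cosine of
#' the polar scattering angle. For `g = 0` this reduces to `2u - 1`
#' (isotropic scattering); the distribution's mean cosine equals `g`.
#'
#' @param g Anisotropy in \[-1, 1\].
#' @param u Uniform deviate(s) in \[0, 1).
#' @return Scattering cosine(s) in \[-1, 1\].
#' @export
sample_hg_cosine <- function(g, u) {
  stopifnot(abs(g) <= 1, all(u >= 0), all(u < 1))
  if (abs(g) < 1e-6) return(2 * u - 1)
  s <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(1, pmax(-1, (1 + g^2 - s^2) / (2 * g)))
}

#' Beer-Lambert transmittance oracle
#'
#' Closed-form on-axis attenuation `exp(-mu_a z)` for a non-scattering
#' medium; used as an independent check of the transport code.
#'
#' @param mu_a Absorption coefficient (1/cm), non-negative.
#' @param z Path length (cm), non-negative.
#' @return Transmittance in (0, 1\].
#' @export
beer_lambert_oracle <- function(mu_a, z) {
  stopifnot(all(mu_a >= 0), all(z >= 0))
  exp(-mu_a * z)
}

#' Fluence from the absorbed-energy map
#'
#' Converts deposited energy to fluence via `F = E / (mu_a V_voxel)`
#' (energy per unit area, in 1/cm^2 per unit launched energy). Voxels with
#' `mu_a = 0` have undefined fluence and are returned as `NA`.
#'
#' @param emap An `absorbed_energy_map`.
#' @param phantom The congruent `optical_phantom`.
#' @return 3-D array of fluence values; `NA` where `mu_a = 0`.
#' @export
fluence_from_energy <- function(emap, phantom) {
  stopifnot(inherits(emap, "absorbed_energy_map"),
            inherits(phantom, "optical_phantom"))
  if (!identical(dim(emap$values), dim(phantom$mu_a)))
    stop("energy map and phantom have mismatched dimensions")
  v_cm3 <- (phantom$voxel_mm / 10)^3
  f <- emap$values / (phantom$mu_a * v_cm3)
  f[phantom$mu_a == 0] <- NA_real_
  f
}

#' Absorbed energy from fluence (inverse of [fluence_from_energy()])
#'
#' @param fluence 3-D fluence array.
#' @param phantom The congruent `optical_phantom`.
#' @return 3-D array of deposited energy per voxel, `E = mu_a F V`.
#' @export
energy_from_fluence <- function(fluence, phantom) {
  stopifnot(inherits(phantom, "optical_phantom"),
            identical(dim(fluence), dim(phantom$mu_a)))
  v_cm3 <- (phantom$voxel_mm / 10)^3
  e <- phantom$mu_a * fluence * v_cm3
  e[phantom$mu_a == 0] <- 0
  e
}
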