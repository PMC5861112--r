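# Acoustic forward modelling: initial pressure from absorbed energy, the
# velocity-potential shell decomposition (the noise/signal model used for
# the temperature sweeps), and impulse spherical-wave superposition for
# point/aperture traces and linear-array RF synthesis.

#' Detector specification
#'
#' @param kind `"point"`, `"square_aperture"` (flat integrating aperture
#'   sampled on a point grid), or `"linear_array"`.
#' @param position `c(x, y, z)` of the detector centre in mm; `z <= 0`
#'   (on or above the illuminated top face, which is `z = 0`).
#' @param aperture_mm2 Aperture area for `"square_aperture"` (default 4 mm^2).
#' @param aperture_points Points per side used to sample the aperture.
#' @param element_count,pitch_mm Linear-array layout (elements along x,
#'   centred on `position`).
#' @param dt_us Sample interval (microseconds).
#' @param record_length Number of time samples; `NULL` sizes the record to
#'   contain the farthest voxel.
#' @return An object of class `detector_spec`.
#' @export
detector_spec <- function(kind = c("point", "square_aperture", "linear_array"),
                          position = c(0, 0, 0), aperture_mm2 = 4,
                          aperture_points = 5L, element_count = 128L,
                          pitch_mm = 0.3, dt_us = 0.1, record_length = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(position) == 3L, dt_us > 0, aperture_mm2 > 0,
            aperture_points >= 1L, element_count >= 1L, pitch_mm > 0)
  if (position[3] > 0) stop("detector must sit on or above the top face (z <= 0)")
  structure(list(kind = kind, position = position, aperture_mm2 = aperture_mm2,
                 aperture_points = as.integer(aperture_points),
                 element_count = as.integer(element_count), pitch_mm = pitch_mm,
                 dt_us = dt_us, record_length = record_length),
            class = "detector_spec")
}

# sampling points (rows of x,y,z in mm) for a detector
.detector_points <- function(det) {
  switch(det$kind,
    point = matrix(det$position, nrow = 1),
    square_aperture = {
      side <- sqrt(det$aperture_mm2)
      n <- det$aperture_points
      u <- (seq_len(n) - (n + 1) / 2) / n * side
      gp <- expand.grid(x = u, y = u)
      cbind(det$position[1] + gp$x, det$position[2] + gp$y, det$position[3])
    },
    linear_array = {
      xe <- (seq_len(det$element_count) - (det$element_count + 1) / 2) * det$pitch_mm
      cbind(det$position[1] + xe, det$position[2], det$position[3])
    })
}

#' Element lateral positions of a linear-array detector (mm)
#' @param det A `detector_spec` of kind `"linear_array"`.
#' @return Numeric vector of element x-positions.
#' @export
element_positions <- function(det) {
  stopifnot(inherits(det, "detector_spec"), det$kind == "linear_array")
  .detector_points(det)[, 1]
}

#' Initial pressure map from absorbed energy
#'
#' `p0 = Gamma * E / V_voxel`: the per-voxel Grueneisen parameter times the
#' deposited energy density. Equivalent to `Gamma * mu_a * F` where the
#' fluence is defined.
#'
#' @param emap An `absorbed_energy_map`.
#' @param phantom The congruent `optical_phantom` with a per-voxel `gamma`
#'   array (see [apply_temperature()]).
#' @return An object of class `initial_pressure_map` with the 3-D array
#'   `p0` (pressure units per unit launched energy) and grid metadata.
#' @export
initial_pressure <- function(emap, phantom) {
  stopifnot(inherits(emap, "absorbed_energy_map"),
            inherits(phantom, "optical_phantom"))
  if (is.null(phantom$gamma))
    stop("phantom has no per-voxel Grueneisen parameter; call apply_temperature() first")
  if (!identical(dim(emap$values), dim(phantom$mu_a)))
    stop("energy map and phantom have mismatched dimensions")
  v_mm3 <- phantom$voxel_mm^3
  structure(list(p0 = phantom$gamma * emap$values / v_mm3,
                 voxel_mm = phantom$voxel_mm,
                 labels = phantom$labels),
            class = "initial_pressure_map")
}

#' Shell decomposition of the absorbed energy
#'
#' Bins voxels into spherical shells of thickness `dr = v_s dt` around the
#' detector: all voxels in shell k contribute pressure that arrives at
#' time `k dt`. Deposited energy is accumulated per shell separately for
#' background-labelled and target-labelled voxels; this is the
#' velocity-potential noise/signal model, in which the trace amplitudes
#' are simply the shell energies scaled by the regional Grueneisen
#' parameters.
#'
#' @param emap An `absorbed_energy_map`.
#' @param phantom Congruent `optical_phantom` (supplies labels and geometry).
#' @param detector A `detector_spec` (`"point"` or `"square_aperture"`, in
#'   which case its centre is used).
#' @param v_s Speed of sound (m/s).
#' @param dt_us Shell time step (microseconds); shell thickness should be
#'   at least about one voxel.
#' @return An object of class `shell_decomposition`: `times` (us),
#'   `e_shell_background`, `e_shell_target` (deposited energy per shell),
#'   voxel counts per shell and a logical `gap` flag for empty shells.
#' @export
shell_decompose <- function(emap, phantom, detector, v_s, dt_us = detector$dt_us) {
  stopifnot(inherits(emap, "absorbed_energy_map"),
            inherits(phantom, "optical_phantom"),
            inherits(detector, "detector_spec"), v_s > 0, dt_us > 0)
  if (detector$kind == "linear_array")
    stop("shell decomposition is defined for point or aperture-centre detectors")
  if (!identical(dim(emap$values), dim(phantom$mu_a)))
    stop("energy map and phantom have mismatched dimensions")
  v_mm_us <- v_s / 1000
  dr <- v_mm_us * dt_us
  if (dr < phantom$voxel_mm / 4)
    warning("shell thickness below a quarter voxel; shells will be sparsely populated")

  co <- phantom_coords(phantom)
  p <- detector$position
  d <- dim(emap$values)
  r <- sqrt(outer(outer((co$x - p[1])^2, (co$y - p[2])^2, `+`),
                  (co$z - p[3])^2, `+`))
  k <- as.integer(floor(r / dr + 0.5))
  nb <- max(k) + 1L
  bg <- phantom$labels != 1L
  acc <- function(sel) {
    out <- numeric(nb)
    s <- rowsum(as.numeric(emap$values[sel]), k[sel])
    i <- as.integer(rownames(s)) + 1L
    out[i] <- s
    out
  }
  counts <- tabulate(k + 1L, nbins = nb)
  structure(list(times = (seq_len(nb) - 1L) * dt_us,
                 e_shell_background = acc(bg),
                 e_shell_target = if (any(!bg)) acc(!bg) else numeric(nb),
                 counts = counts, gap = counts == 0L,
                 dt_us = dt_us, v_s = v_s, dr_mm = dr),
            class = "shell_decomposition")
}

#' Construct a pressure trace
#' @param times Sample times (us), strictly increasing.
#' @param values Amplitudes (arbitrary pressure units).
#' @param provenance One of `"true"`, `"noise"`, `"signal"`.
#' @return An object of class `pa_trace`.
#' @export
pa_trace <- function(times, values, provenance = c("true", "noise", "signal")) {
  provenance <- match.arg(provenance)
  stopifnot(length(times) == length(values), all(is.finite(values)),
            all(diff(times) > 0))
  structure(list(times = times, values = values, provenance = provenance),
            class = "pa_trace")
}

#' Noise and signal traces from a shell decomposition
#'
#' The background trace is `Gamma_outside * E_shell_background(t)` and the
#' target trace `Gamma_inside * E_shell_target(t)`: each is exactly linear
#' in its own Grueneisen parameter and independent of the other region's,
#' which is the mechanism by which cooling the intermediate medium lowers
#' the noise floor while leaving the target signal untouched.
#'
#' @param shells A [shell_decompose()] result.
#' @param gamma_outside Grueneisen parameter of the intermediate medium.
#' @param gamma_inside Grueneisen parameter of the target.
#' @return List with `pa_noise` and `pa_signal` traces (`pa_trace`).
#' @export
pa_trace_shell <- function(shells, gamma_outside, gamma_inside) {
  stopifnot(inherits(shells, "shell_decomposition"),
            gamma_outside >= 0, gamma_inside >= 0)
  list(pa_noise = pa_trace(shells$times, gamma_outside * shells$e_shell_background,
                           "noise"),
       pa_signal = pa_trace(shells$times, gamma_inside * shells$e_shell_target,
                            "signal"))
}

#' Spherical-wave superposition forward model
#'
#' Treats every voxel as an impulsive spherical source in a homogeneous
#' lossless medium: its contribution arrives at `t = r / v_s` and the
#' pressure is recovered as the time derivative of the accumulated
#' velocity-potential-like quantity (`p = -rho d(phi)/dt`), yielding the
#' bipolar waveform. Aperture detectors average the trace over sampled
#' points on the face; a linear array returns one trace per element.
#'
#' @param p0map An [initial_pressure()] result.
#' @param detector A `detector_spec`.
#' @param v_s Speed of sound (m/s).
#' @param dt_us Sample interval (us); defaults to the detector's.
#' @param record_length Number of samples; `NULL` auto-sizes to contain the
#'   farthest voxel. A record too short to contain it triggers a warning.
#' @return For point/aperture detectors a `pa_trace`; for a linear array an
#'   `rf_frameset` with one noise-free frame (matrix elements x samples).
#' @export
pa_trace_superposition <- function(p0map, detector, v_s,
                                   dt_us = detector$dt_us,
                                   record_length = detector$record_length) {
  stopifnot(inherits(p0map, "initial_pressure_map"),
            inherits(detector, "detector_spec"), v_s > 0, dt_us > 0)
  d <- dim(p0map$p0)
  h <- p0map$voxel_mm
  coords <- list(x = (seq_len(d[1]) - 0.5) * h - d[1] * h / 2,
                 y = (seq_len(d[2]) - 0.5) * h - d[2] * h / 2,
                 z = (seq_len(d[3]) - 0.5) * h)
  v_mm_us <- v_s / 1000
  pts <- .detector_points(detector)
  # farthest voxel corner from any detector point
  corner <- c(max(abs(range(coords$x))) + h / 2, max(abs(range(coords$y))) + h / 2,
              max(coords$z) + h / 2)
  rmax <- max(sqrt((abs(pts[, 1]) + corner[1])^2 + (abs(pts[, 2]) + corner[2])^2 +
                   (abs(pts[, 3]) + corner[3])^2))
  need <- ceiling(rmax / (v_mm_us * dt_us)) + 3L
  if (is.null(record_length)) record_length <- need
  else if (record_length < need)
    warning("record too short to contain the farthest voxel; trace is truncated")

  traces <- .superpose_cpp(as.numeric(p0map$p0), as.integer(d), h,
                           coords$x, coords$y, coords$z,
                           pts, v_mm_us, dt_us, as.integer(record_length))
  times <- seq_len(record_length) * dt_us
  if (detector$kind == "linear_array") {
    rf_frameset(traces, element_x = pts[, 1], dt_us = dt_us, v_s = v_s)
  } else {
    pa_trace(times, colMeans(traces), "true")
  }
}

#' Closed-form N-wave of a uniform spherical absorber
#'
#' The pressure observed at distance `r` from the centre of a uniformly
#' pressurised sphere of radius `a` is the bipolar
#' `p0 (r - v t) / (2 r)` for `|r - v t| <= a` and zero elsewhere; the
#' standard analytic test case for photoacoustic forward models.
#'
#' @param p0 Initial pressure inside the sphere.
#' @param a Sphere radius (mm).
#' @param r Observer distance from the sphere centre (mm), `r > a`.
#' @param v_s Speed of sound (m/s).
#' @param t Time(s) in microseconds.
#' @return Pressure at each `t` (same units as `p0`).
#' @export
nwave_analytic <- function(p0, a, r, v_s, t) {
  stopifnot(r > a, a > 0, v_s > 0)
  v <- v_s / 1000
  u <- r - v * t
  ifelse(abs(u) <= a, p0 * u / (2 * r), 0)
}
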