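# Signal-to-noise metrics: trace-domain SNR at the arrival time t = z/v,
# the analytic temperature-difference prediction
# dSNR = 10 log10 |Gamma(T1)/Gamma(T2)|, and image-domain SNR
# 10 log10(max(I^2)/var(background)).

#' Trace amplitude at the target arrival time
#'
#' Evaluates a trace at `t = depth / v_s` as the maximum absolute value
#' within a gate of +/- `gate` samples around the arrival sample (discrete
#' sampling makes a point evaluation ill-defined); returns the signed
#' value at the gated maximum.
#'
#' @param trace A `pa_trace`.
#' @param depth_mm Target depth (mm).
#' @param v_s Speed of sound (m/s).
#' @param gate Half-width of the gate in samples (default 3).
#' @return Amplitude at the gate maximum.
#' @export
trace_amplitude_at <- function(trace, depth_mm, v_s, gate = 3L) {
  stopifnot(inherits(trace, "pa_trace"), depth_mm > 0, v_s > 0)
  t_arr <- depth_mm / (v_s / 1000)
  dt <- trace$times[2] - trace$times[1]
  k <- round((t_arr - trace$times[1]) / dt) + 1
  if (k < 1 || k > length(trace$values))
    stop("arrival time lies outside the recorded trace")
  win <- max(1, k - gate):min(length(trace$values), k + gate)
  v <- trace$values[win]
  v[which.max(abs(v))]
}

#' Split a measured trace into signal and noise at the arrival gate
#'
#' Implements the subtraction protocol: the acquisition with the target in
#' place gives `PA_true`, the target-free acquisition gives `PA_noise`, and
#' the target's own contribution is `PA_signal = PA_true - PA_noise`, all
#' evaluated at the arrival gate `t = z / v_s`.
#'
#' @param trace_true Trace with the target present.
#' @param trace_noise Trace from the same fluence realization with the
#'   target's sources removed (shared-fluence protocol), so the
#'   subtraction isolates the target contribution exactly.
#' @param depth_mm Target depth (mm).
#' @param v_s Speed of sound (m/s).
#' @param gate Gate half-width in samples.
#' @details The signal amplitude is extracted from the difference trace
#' `true - noise` (not as a difference of separately gated maxima): the
#' gated maxima of the two traces can sit at different samples, which
#' would leak background into the signal estimate. With the difference
#' gated directly, the signal is exactly the target contribution whenever
#' the two traces share one fluence realization.
#'
#' @return List with `pa_true`, `pa_noise`, `pa_signal` amplitudes and the
#'   arrival time `t_us`.
#' @export
signal_noise_split <- function(trace_true, trace_noise, depth_mm, v_s, gate = 3L) {
  stopifnot(inherits(trace_true, "pa_trace"), inherits(trace_noise, "pa_trace"))
  if (!isTRUE(all.equal(trace_true$times, trace_noise$times)))
    stop("traces must share the same time axis")
  a_true <- trace_amplitude_at(trace_true, depth_mm, v_s, gate)
  a_noise <- trace_amplitude_at(trace_noise, depth_mm, v_s, gate)
  diff_tr <- pa_trace(trace_true$times, trace_true$values - trace_noise$values,
                      "signal")
  list(pa_true = a_true, pa_noise = a_noise,
       pa_signal = trace_amplitude_at(diff_tr, depth_mm, v_s, gate),
       t_us = depth_mm / (v_s / 1000))
}

#' Trace-domain SNR in dB
#'
#' `10 log10 |pa_signal / pa_noise|`. Signs are ignored; a zero noise
#' amplitude returns `Inf` (a sentinel, not an error).
#'
#' @param pa_signal,pa_noise Amplitudes.
#' @return SNR in dB.
#' @export
snr_db <- function(pa_signal, pa_noise) {
  ifelse(pa_noise == 0, Inf, 10 * log10(abs(pa_signal / pa_noise)))
}

#' Analytic SNR change between two medium temperatures
#'
#' The background amplitude is proportional to the intermediate-medium
#' Grueneisen parameter while the target amplitude is fixed, so
#' `SNR(T2) - SNR(T1) = 10 log10 |Gamma(T1) / Gamma(T2)|`. This closed
#' form is the oracle the simulated gamma-only sweep must match exactly
#' under the shared-fluence protocol.
#'
#' @param T1,T2 Temperatures (degC); the convention is
#'   `dSNR = SNR(T2) - SNR(T1)`.
#' @param model A [thermo_model()].
#' @return dSNR in dB (positive when `T2` is the colder state).
#' @export
delta_snr_analytic <- function(T1, T2, model) {
  10 * log10(abs(grueneisen_scale(T1, model) / grueneisen_scale(T2, model)))
}

#' Image-domain SNR in dB
#'
#' `10 log10(max(I^2) / var_background)`: the squared image peak against
#' the pixel variance over a background region. By default the background
#' is every pixel farther than `exclude_mm` from the detected peak,
#' excluding a border of `border_mm`.
#'
#' @param image A `reconstructed_image`.
#' @param background Optional logical mask (same shape as the image) of
#'   background pixels; overrides the default region.
#' @param exclude_mm Radius around the detected peak excluded from the
#'   background (default 3 mm).
#' @param border_mm Image border excluded from the background (default 1 mm).
#' @param roi Optional logical mask restricting the peak search (the
#'   imaging-target region of interest); the background is everything far
#'   from the detected peak. Without it the global image maximum is used,
#'   which in a full-field photoacoustic image can be shallow clutter
#'   rather than the target.
#' @return SNR in dB; `Inf` if the background variance is zero.
#' @export
image_snr <- function(image, background = NULL, exclude_mm = 3, border_mm = 1,
                      roi = NULL) {
  stopifnot(inherits(image, "reconstructed_image"))
  I <- image$pixels
  Isearch <- I
  if (!is.null(roi)) {
    stopifnot(identical(dim(roi), dim(I)), any(roi))
    Isearch[!roi] <- 0
  }
  pk <- which(abs(Isearch) == max(abs(Isearch)), arr.ind = TRUE)[1, ]
  if (is.null(background)) {
    dx <- outer(image$x - image$x[pk[1]], rep(1, length(image$z)))
    dz <- outer(rep(1, length(image$x)), image$z - image$z[pk[2]])
    far <- sqrt(dx^2 + dz^2) > exclude_mm
    inx <- image$x > min(image$x) + border_mm & image$x < max(image$x) - border_mm
    inz <- image$z > min(image$z) + border_mm & image$z < max(image$z) - border_mm
    background <- far & outer(inx, inz, `&`)
  } else {
    stopifnot(identical(dim(background), dim(I)))
    if (background[pk[1], pk[2]])
      stop("background mask must exclude the detected peak")
  }
  if (!any(background)) stop("empty background region")
  s2 <- stats::var(as.numeric(I[background]))
  if (s2 == 0) return(Inf)
  10 * log10(I[pk[1], pk[2]]^2 / s2)
}
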