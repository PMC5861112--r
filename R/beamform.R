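# Image reconstruction from linear-array RF: delay-and-sum (DAS),
# delay-multiply-and-sum (DMAS) and double-stage DMAS (DS-DMAS).
# DMAS at a pixel is the sum over element pairs i < j of
# sign(s_i s_j) sqrt(|s_i s_j|); with the signed-root transform
# shat = sign(s) sqrt(|s|) this equals ((sum shat)^2 - sum shat^2) / 2,
# which is what the implementation computes (O(N) per pixel).

#' Image grid for beamforming
#'
#' @param x_mm,z_mm Pixel centre coordinates: lateral (array axis) and
#'   depth below the array plane (mm). Depths must be positive.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(x_mm, z_mm) {
  stopifnot(all(z_mm > 0), length(x_mm) >= 1L, length(z_mm) >= 1L)
  structure(list(x = x_mm, z = z_mm), class = "image_grid")
}

#' Per-pixel, per-element delay table
#'
#' One-way time-of-flight delays in fractional samples from every pixel to
#' every element: `delay = dist / (v_s dt)`. Delays beyond the RF record
#' are flagged (`NA`) and the affected pixels are treated as invalid by the
#' beamformers.
#'
#' @param grid An [image_grid()].
#' @param element_x Element lateral positions (mm), at depth 0.
#' @param v_s Speed of sound (m/s).
#' @param dt_us Sample interval (us).
#' @param n_samples Record length used to flag out-of-record delays
#'   (optional).
#' @return Array `length(x) x length(z) x n_elements` of fractional sample
#'   delays.
#' @export
delay_table <- function(grid, element_x, v_s, dt_us, n_samples = NULL) {
  stopifnot(inherits(grid, "image_grid"), v_s > 0, dt_us > 0)
  v <- v_s / 1000
  nxp <- length(grid$x); nzp <- length(grid$z); ne <- length(element_x)
  del <- array(0, dim = c(nxp, nzp, ne))
  for (e in seq_len(ne)) {
    dist <- sqrt(outer((grid$x - element_x[e])^2, grid$z^2, `+`))
    del[, , e] <- dist / (v * dt_us)
  }
  if (!is.null(n_samples)) del[del > n_samples - 1] <- NA_real_
  del
}

# delayed sample matrix for one frame: pixels x elements, linear interp
.delayed_samples <- function(frame, del) {
  nxp <- dim(del)[1]; nzp <- dim(del)[2]; ne <- dim(del)[3]
  ns <- ncol(frame)
  out <- matrix(0, nrow = nxp * nzp, ncol = ne)
  for (e in seq_len(ne)) {
    d <- as.numeric(del[, , e])
    # RF sample j corresponds to time j*dt, so the fractional sample
    # position d sits between samples floor(d) and floor(d)+1
    k <- floor(d)
    f <- d - k
    k <- as.integer(k)
    lo <- ifelse(is.na(k) | k < 1L | k > ns, NA_real_, frame[e, pmax(pmin(k, ns), 1L)])
    hi <- ifelse(is.na(k) | k + 1L < 1L | k + 1L > ns, NA_real_,
                 frame[e, pmax(pmin(k + 1L, ns), 1L)])
    out[, e] <- (1 - f) * lo + f * hi
  }
  out[is.na(out)] <- 0
  out
}

.as_image <- function(vals, grid) {
  structure(list(pixels = matrix(vals, nrow = length(grid$x)),
                 x = grid$x, z = grid$z),
            class = "reconstructed_image")
}

#' @export
print.reconstructed_image <- function(x, ...) {
  cat(sprintf("reconstructed_image: %d x %d pixels, peak %.3g\n",
              nrow(x$pixels), ncol(x$pixels), max(abs(x$pixels))))
  invisible(x)
}

# signed square root
.sroot <- function(s) sign(s) * sqrt(abs(s))

# pairwise DMAS via the signed-root identity
.dmas_combine <- function(shat) {
  tot <- rowSums(shat)
  (tot^2 - rowSums(shat^2)) / 2
}

#' Delay-and-sum beamforming
#'
#' @param rf An [rf_frameset()].
#' @param grid An [image_grid()].
#' @param frame Frame index to reconstruct.
#' @return A `reconstructed_image`.
#' @export
das <- function(rf, grid, frame = 1L) {
  stopifnot(inherits(rf, "rf_frameset"))
  del <- delay_table(grid, rf$element_x, rf$v_s, rf$dt_us, dim(rf$frames)[2])
  s <- .delayed_samples(rf$frames[, , frame], del)
  .as_image(rowSums(s), grid)
}

#' Delay-multiply-and-sum beamforming
#'
#' Pairwise DMAS: pixel value `sum_{i<j} sign(s_i s_j) sqrt(|s_i s_j|)`
#' over the delayed element samples. Suppresses incoherent clutter
#' relative to DAS because uncorrelated pair products average out.
#'
#' @inheritParams das
#' @return A `reconstructed_image`.
#' @export
dmas <- function(rf, grid, frame = 1L) {
  stopifnot(inherits(rf, "rf_frameset"), dim(rf$frames)[1] >= 2L)
  del <- delay_table(grid, rf$element_x, rf$v_s, rf$dt_us, dim(rf$frames)[2])
  s <- .delayed_samples(rf$frames[, , frame], del)
  .as_image(.dmas_combine(.sroot(s)), grid)
}

#' Double-stage delay-multiply-and-sum beamforming
#'
#' Stage 1 applies pairwise DMAS within each subaperture of consecutive
#' elements; stage 2 applies pairwise DMAS across the stage-1 outputs.
#' With a single subaperture spanning the whole array the second stage is
#' the identity and the result reduces to single-stage DMAS.
#'
#' @inheritParams das
#' @param subaperture Elements per stage-1 group (default 8); must be >= 2
#'   and leave at least one group.
#' @return A `reconstructed_image`.
#' @export
ds_dmas <- function(rf, grid, frame = 1L, subaperture = 8L) {
  stopifnot(inherits(rf, "rf_frameset"))
  ne <- dim(rf$frames)[1]
  if (subaperture < 2L) stop("`subaperture` must be at least 2 elements")
  groups <- split(seq_len(ne), ceiling(seq_len(ne) / subaperture))
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) < 1L) stop("subaperture leaves no usable group")
  del <- delay_table(grid, rf$element_x, rf$v_s, rf$dt_us, dim(rf$frames)[2])
  s <- .delayed_samples(rf$frames[, , frame], del)
  shat <- .sroot(s)
  stage1 <- vapply(groups, function(g) .dmas_combine(shat[, g, drop = FALSE]),
                   numeric(nrow(s)))
  if (length(groups) == 1L) return(.as_image(stage1[, 1], grid))
  .as_image(.dmas_combine(.sroot(stage1)), grid)
}

#' Hilbert envelope of a reconstructed image (per depth line)
#'
#' Optional post-processing: magnitude of the analytic signal along each
#' depth line, computed with an FFT.
#'
#' @param image A `reconstructed_image`.
#' @return A `reconstructed_image` of non-negative envelope values.
#' @export
envelope_image <- function(image) {
  stopifnot(inherits(image, "reconstructed_image"))
  env <- apply(image$pixels, 1, function(sig) {
    n <- length(sig)
    H <- numeric(n)
    if (n %% 2 == 0) {
      H[c(1, n / 2 + 1)] <- 1
      H[2:(n / 2)] <- 2
    } else {
      H[1] <- 1
      H[2:((n + 1) / 2)] <- 2
    }
    Mod(stats::fft(stats::fft(sig) * H, inverse = TRUE) / n)
  })
  out <- image
  out$pixels <- t(env)
  out
}
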