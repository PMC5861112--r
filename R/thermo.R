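# Temperature scaling of the thermoacoustic and optical properties that
# drive the rest of the pipeline: the Grueneisen parameter of the
# intermediate medium, its reduced scattering coefficient, and the speed
# of sound used to convert depth to arrival time.

#' Thermophysical properties of an acoustic medium
#'
#' Bundles the quantities that determine the Grueneisen parameter
#' \eqn{\Gamma = \beta v_s^2 / C_p} together with density and an optional
#' scalar acoustic attenuation factor.
#'
#' @param beta Volumetric thermal expansion coefficient (1/K). May be
#'   negative (water below 4 degC).
#' @param v_s Speed of sound (m/s), strictly positive.
#' @param c_p Specific heat at constant pressure (J/(kg K)), strictly positive.
#' @param rho Mass density (kg/m^3), strictly positive.
#' @param xi Dimensionless acoustic attenuation factor in (0, 1]. The default
#'   1 means attenuation is ignored.
#'
#' @return An object of class `medium_properties`.
#' @examples
#' water20 <- medium_properties(beta = 2.07e-4, v_s = 1482, c_p = 4182)
#' grueneisen_from_properties(water20)
#' @export
medium_properties <- function(beta, v_s, c_p, rho = 1000, xi = 1) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (!is.numeric(v_s) || v_s <= 0) stop("`v_s` must be strictly positive")
  if (!is.numeric(c_p) || c_p <= 0) stop("`c_p` must be strictly positive")
  if (!is.numeric(rho) || rho <= 0) stop("`rho` must be strictly positive")
  if (!is.numeric(xi) || xi <= 0 || xi > 1) stop("`xi` must lie in (0, 1]")
  structure(list(beta = beta, v_s = v_s, c_p = c_p, rho = rho, xi = xi),
            class = "medium_properties")
}

#' Grueneisen parameter from medium properties
#'
#' Evaluates \eqn{\Gamma = \beta v_s^2 / C_p}: the dimensionless efficiency
#' with which absorbed optical energy is converted into initial pressure.
#'
#' @param props A [medium_properties()] object.
#' @return Dimensionless Grueneisen parameter.
#' @export
grueneisen_from_properties <- function(props) {
  stopifnot(inherits(props, "medium_properties"))
  if (props$c_p <= 0) stop("heat capacity must be positive")
  props$beta * props$v_s^2 / props$c_p
}

# Supported temperature range (degC). Linear percentage rates for Gamma and
# mus' are only backed by measurements well below the protein-coagulation
# regime, so evaluation outside this window is refused.
.t_range <- c(0, 45)

#' Temperature scaling model for Grueneisen parameter and reduced scattering
#'
#' Anchored linear scaling laws: a property at temperature `T` equals its
#' reference value times `1 + rate * (T - t_ref)`. The defaults encode a
#' 1.5 %/degC fractional change of the Grueneisen parameter and a
#' 0.4 %/degC change of the reduced scattering coefficient of soft tissue,
#' both increasing with temperature. A per-degree compounding variant
#' `(1 + rate)^(T - t_ref)` is available via `compounding = TRUE`; result
#' tables record which convention was used.
#'
#' @param gamma_ref Grueneisen value at the anchor temperature.
#' @param t_ref Anchor temperature (degC) at which every scaling factor is
#'   exactly 1. Default 20 degC, the midpoint of the 5-35 degC sweep.
#' @param rate_gamma Fractional change of Gamma per degC (default 0.015).
#' @param rate_mus Fractional change of mus' per degC (default 0.004).
#' @param vs_model Either `"constant"` (use `vs_value` at all temperatures)
#'   or `"water_polynomial"` (Marczak's fifth-order polynomial for the speed
#'   of sound in pure water).
#' @param vs_value Speed of sound (m/s) used in `"constant"` mode.
#' @param compounding Use per-degree compounding instead of the linear
#'   anchor convention.
#'
#' @return An object of class `thermo_model`.
#' @export
thermo_model <- function(gamma_ref = 0.2, t_ref = 20,
                         rate_gamma = 0.015, rate_mus = 0.004,
                         vs_model = c("constant", "water_polynomial"),
                         vs_value = 1500, compounding = FALSE) {
  vs_model <- match.arg(vs_model)
  stopifnot(is.numeric(gamma_ref), gamma_ref > 0,
            is.numeric(t_ref), t_ref >= .t_range[1], t_ref <= .t_range[2],
            is.numeric(rate_gamma), is.numeric(rate_mus),
            is.numeric(vs_value), vs_value > 0,
            is.logical(compounding), length(compounding) == 1L)
  m <- structure(list(gamma_ref = gamma_ref, t_ref = t_ref,
                      rate_gamma = rate_gamma, rate_mus = rate_mus,
                      vs_model = vs_model, vs_value = vs_value,
                      compounding = compounding),
                 class = "thermo_model")
  # Gamma must stay positive over the whole supported range.
  sc <- vapply(.t_range, function(T) .aniso_scale(T, t_ref, rate_gamma, compounding),
               numeric(1))
  if (any(sc <= 0)) stop("`rate_gamma` drives Gamma non-positive inside [0, 45] degC")
  m
}

.check_temperature <- function(T) {
  if (!is.numeric(T) || any(!is.finite(T)))
    stop("temperature must be finite numeric")
  if (any(T < .t_range[1] | T > .t_range[2]))
    stop(sprintf("temperature outside supported range [%g, %g] degC",
                 .t_range[1], .t_range[2]))
  invisible(T)
}

.aniso_scale <- function(T, t_ref, rate, compounding) {
  if (compounding) (1 + rate)^(T - t_ref) else 1 + rate * (T - t_ref)
}

#' Grueneisen scaling factor at a temperature
#'
#' Returns \eqn{\Gamma(T) / \Gamma(t_{ref})} under the model's convention
#' (linear anchor by default). Strictly increasing in `T` for positive rates.
#'
#' @param T Temperature(s) in degC, inside \[0, 45\].
#' @param model A [thermo_model()].
#' @return Dimensionless scaling factor(s), exactly 1 at `t_ref`.
#' @examples
#' m <- thermo_model()
#' grueneisen_scale(21, m)  # 1.015
#' @export
grueneisen_scale <- function(T, model) {
  stopifnot(inherits(model, "thermo_model"))
  .check_temperature(T)
  s <- .aniso_scale(T, model$t_ref, model$rate_gamma, model$compounding)
  if (any(s <= 0)) stop("Grueneisen scaling factor non-positive at requested temperature")
  s
}

#' Reduced scattering coefficient at a temperature
#'
#' Scales a reference reduced scattering coefficient with temperature:
#' `mus_ref * (1 + rate_mus * (T - t_ref))` (or the compounding analogue).
#' Soft tissue scatters less when cooled, which lets more fluence reach a
#' deep target.
#'
#' @inheritParams grueneisen_scale
#' @param mus_ref Reference reduced scattering coefficient (1/cm), positive.
#' @return mus' at `T` in 1/cm.
#' @export
reduced_scattering_at <- function(T, mus_ref, model) {
  stopifnot(inherits(model, "thermo_model"), is.numeric(mus_ref), all(mus_ref > 0))
  .check_temperature(T)
  out <- mus_ref * .aniso_scale(T, model$t_ref, model$rate_mus, model$compounding)
  if (any(out <= 0)) stop("scaled mus' is non-positive; temperature/rate out of validity")
  out
}

# Marczak (1997) fifth-order polynomial for the speed of sound in pure
# water at atmospheric pressure, T in degC, result in m/s. Monotone
# increasing over [0, 45] degC (its maximum sits near 74 degC).
.water_vs_coef <- c(1.402385e3, 5.038813, -5.799136e-2,
                    3.287156e-4, -1.398845e-6, 2.787860e-9)

#' Speed of sound at a temperature
#'
#' `"constant"` mode returns the configured value irrespective of `T`;
#' `"water_polynomial"` mode evaluates a standard fifth-order polynomial
#' fit for pure water (about 1482 m/s at 20 degC).
#'
#' @inheritParams grueneisen_scale
#' @return Speed of sound in m/s.
#' @export
speed_of_sound_at <- function(T, model) {
  stopifnot(inherits(model, "thermo_model"))
  .check_temperature(T)
  switch(model$vs_model,
         constant = rep_len(model$vs_value, length(T)),
         water_polynomial = {
           p <- outer(T, 0:5, `^`)
           as.numeric(p %*% .water_vs_coef)
         },
         stop("unknown speed-of-sound mode: ", model$vs_model))
}

#' Apply per-region temperatures to a phantom
#'
#' Sets the per-voxel Grueneisen parameter and (optionally) rescales the
#' scattering coefficient of an optical phantom according to a thermal
#' scenario. The phantom must be in its reference state (as produced by
#' [build_slab_rod_phantom()]); scaling is always relative to `t_ref`.
#'
#' Scenarios mirror the three simulation sets of the study:
#' `"gamma_only"` scales only the intermediate-medium Grueneisen parameter,
#' `"mus_only"` scales only its scattering, `"both"` scales both. The
#' target's Grueneisen parameter follows the target temperature (pinned at
#' 37 degC in the standard sweep) in every scenario, so it is identical
#' across a sweep in which only the medium temperature changes.
#'
#' @param phantom An `optical_phantom` in reference state.
#' @param temps Named numeric vector with elements `medium` and `target`
#'   (degC).
#' @param model A [thermo_model()].
#' @param scenario One of `"both"`, `"gamma_only"`, `"mus_only"`.
#' @return The phantom with a per-voxel `gamma` array, possibly rescaled
#'   `mu_s`, and a `thermal` attribute recording the applied state.
#' @export
apply_temperature <- function(phantom, temps, model,
                              scenario = c("both", "gamma_only", "mus_only")) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(phantom, "optical_phantom"), inherits(model, "thermo_model"))
  if (is.null(names(temps)) || !all(c("medium", "target") %in% names(temps)))
    stop("`temps` must be a named vector with elements 'medium' and 'target'")
  .check_temperature(temps)

  medium <- phantom$labels == 0L
  target <- phantom$labels == 1L

  g_medium <- if (scenario == "mus_only") 1 else grueneisen_scale(temps[["medium"]], model)
  g_target <- grueneisen_scale(temps[["target"]], model)

  gam <- array(model$gamma_ref * g_medium, dim = dim(phantom$mu_a))
  gam[target] <- model$gamma_ref * g_target
  phantom$gamma <- gam

  if (scenario %in% c("mus_only", "both")) {
    f <- reduced_scattering_at(temps[["medium"]], 1, model)
    mu_s <- phantom$mu_s
    mu_s[medium] <- mu_s[medium] * f
    phantom$mu_s <- mu_s
  }

  phantom$thermal <- list(temps = temps, scenario = scenario,
                          convention = if (model$compounding) "compound" else "linear",
                          t_ref = model$t_ref, gamma_ref = model$gamma_ref,
                          rate_gamma = model$rate_gamma, rate_mus = model$rate_mus)
  phantom
}
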