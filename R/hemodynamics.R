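# Closed-form hemodynamic relations: Moens-Korteweg (MK) wave speed,
# pressure-dependent Young's modulus, the log-PTT regression model, and the
# P-beta model with systolic/diastolic tracking.

#' Arterial geometry and blood properties
#'
#' Container for the arterial dimensions entering the Moens-Korteweg and
#' P-beta relations. All lengths are in metres, density in kg/m^3.
#'
#' @param Dd End-diastolic lumen diameter (m).
#' @param deltaD Diameter excursion `Ds - Dd` over the cardiac cycle (m),
#'   non-negative.
#' @param h Wall thickness / intima-media thickness (m).
#' @param D Representative instantaneous diameter (m). Defaults to `Dd`:
#'   systolic and diastolic diameters differ by less than 10% over a cycle,
#'   so the end-diastolic diameter stands in for the instantaneous one.
#' @param rho_blood Whole-blood density (kg/m^3); default 1060 (1.06 g/mL).
#'
#' @return An object of class `arterial_state` with fields `Dd`, `Ds`,
#'   `deltaD`, `D`, `h`, `rho_blood`.
#' @examples
#' arterial_state(Dd = 2.5e-3, deltaD = 1.5e-4, h = 3e-4)
#' @export
arterial_state <- function(Dd, deltaD = 0, h, D = Dd, rho_blood = 1060) {
  check_scalar(Dd, "Dd")
  check_scalar(h, "h")
  check_scalar(D, "D")
  check_scalar(rho_blood, "rho_blood")
  check_scalar(deltaD, "deltaD", positive = FALSE)
  if (deltaD < 0) abort_invalid("'deltaD' must be >= 0")
  if (deltaD / Dd >= 0.10) {
    warning("deltaD/Dd >= 10%: outside the physiological range the ",
            "diameter approximations assume", call. = FALSE)
  }
  structure(
    list(Dd = Dd, Ds = Dd + deltaD, deltaD = deltaD, D = D, h = h,
         rho_blood = rho_blood),
    class = "arterial_state"
  )
}

#' Arterial stiffness parameters
#'
#' @param E0 Young's modulus coefficient (Pa): the modulus at zero pressure.
#' @param xi Exponential pressure coefficient of Young's modulus (1/mmHg).
#' @param beta Local arterial stiffness constant of the P-beta model
#'   (dimensionless), assumed pressure-independent over a measurement.
#' @param k Diastolic/mean tracking coefficient, `DBP = k * MAP`;
#'   default 0.76.
#'
#' @return An object of class `stiffness_params`.
#' @export
stiffness_params <- function(E0, xi, beta = NA_real_, k = 0.76) {
  check_scalar(E0, "E0")
  check_scalar(xi, "xi", positive = FALSE)
  if (!is.na(beta)) check_scalar(beta, "beta")
  check_scalar(k, "k")
  if (k > 1) abort_invalid("'k' must be in (0, 1]")
  structure(list(E0 = E0, xi = xi, beta = beta, k = k),
            class = "stiffness_params")
}

#' Log-PTT regression coefficients
#'
#' Coefficients of the model `P = K1 * ln(PTT) + K2` (pressure in mmHg,
#' PTT in seconds). After fitting on physiological data `K1` is expected to
#' be negative: pressure falls as transit time rises.
#'
#' @param K1 Slope on `ln(PTT)` (mmHg).
#' @param K2 Intercept (mmHg).
#' @return An object of class `regression_coeffs`.
#' @export
regression_coeffs <- function(K1, K2) {
  check_scalar(K1, "K1", positive = FALSE)
  check_scalar(K2, "K2", positive = FALSE)
  structure(list(K1 = K1, K2 = K2), class = "regression_coeffs")
}

#' Blood-pressure estimate
#'
#' @param sbp,dbp,map Systolic, diastolic and mean arterial pressure (mmHg).
#' @param pp Pulse pressure (mmHg); reported alongside but not used by the
#'   default tracking step.
#' @param method `"regression"` or `"p_beta"`.
#' @param valid Quality flag; `FALSE` marks estimates that violate the
#'   `sbp >= map >= dbp` ordering (possible for independently regressed
#'   pressures) or failed a quality gate.
#' @return An object of class `bp_estimate`.
#' @export
bp_estimate <- function(sbp, dbp, map, pp = NA_real_,
                        method = c("p_beta", "regression"), valid = TRUE) {
  method <- match.arg(method)
  ordered <- is.finite(sbp) && is.finite(dbp) && is.finite(map) &&
    sbp >= map && map >= dbp
  structure(
    list(sbp = sbp, dbp = dbp, map = map, pp = pp, method = method,
         valid = isTRUE(valid) && ordered),
    class = "bp_estimate"
  )
}

#' @export
print.bp_estimate <- function(x, ...) {
  cat(sprintf("<bp_estimate [%s]%s> SBP %.1f  DBP %.1f  MAP %.1f mmHg",
              x$method, if (x$valid) "" else " INVALID",
              x$sbp, x$dbp, x$map))
  if (is.finite(x$pp)) cat(sprintf("  (PP %.1f)", x$pp))
  cat("\n")
  invisible(x)
}

#' Pulse wave velocity from transit time
#'
#' `PWV = L / PTT` for an inter-sensor distance `L` along the artery.
#'
#' @param sensor_distance Distance between the two sensing sites (m).
#' @param ptt Pulse transit time (s).
#' @return Wave speed (m/s).
#' @export
pwv_from_ptt <- function(sensor_distance, ptt) {
  check_scalar(sensor_distance, "sensor_distance")
  if (!is.numeric(ptt) || any(!is.finite(ptt)) || any(ptt <= 0)) {
    abort_invalid("'ptt' must be positive and finite (unusable beat pairing)")
  }
  sensor_distance / ptt
}

#' Moens-Korteweg wave speed
#'
#' `PWV = sqrt(E * h / (D * rho))`: wave speed from Young's modulus `E`,
#' wall thickness `h`, diameter `D` and blood density `rho`.
#'
#' @param state An [arterial_state()].
#' @param E Young's modulus (Pa).
#' @return Wave speed (m/s).
#' @export
mk_pwv <- function(state, E) {
  stopifnot(inherits(state, "arterial_state"))
  if (!is.numeric(E) || any(!is.finite(E)) || any(E <= 0)) {
    abort_invalid("'E' must be > 0")
  }
  sqrt(E * state$h / (state$D * state$rho_blood))
}

#' Pressure-dependent Young's modulus
#'
#' `E = E0 * exp(xi * P)` with pressure in mmHg. Strictly increasing in
#' pressure when `xi > 0`.
#'
#' @param params A [stiffness_params()].
#' @param pressure Pressure (mmHg); may be a vector.
#' @return Young's modulus (Pa).
#' @export
youngs_modulus <- function(params, pressure) {
  stopifnot(inherits(params, "stiffness_params"))
  params$E0 * exp(params$xi * pressure)
}

#' Pressure from wave speed (inverse Moens-Korteweg)
#'
#' Exact algebraic inverse of [mk_pwv()] composed with [youngs_modulus()]:
#' `P = ln(PWV^2 * rho * D / (h * E0)) / xi`. The resulting pressure
#' approximates mean arterial pressure.
#'
#' @param state An [arterial_state()].
#' @param params A [stiffness_params()]; `xi` must be non-zero.
#' @param pwv Wave speed (m/s).
#' @return Pressure (mmHg).
#' @export
mk_pressure <- function(state, params, pwv) {
  stopifnot(inherits(state, "arterial_state"),
            inherits(params, "stiffness_params"))
  if (params$xi == 0) abort_invalid("'xi' must be non-zero to invert")
  if (!is.numeric(pwv) || any(!is.finite(pwv)) || any(pwv <= 0)) {
    abort_invalid("'pwv' must be > 0")
  }
  arg <- pwv^2 * state$rho_blood * state$D / (state$h * params$E0)
  if (any(arg <= 0)) abort_invalid("log argument must be > 0")
  log(arg) / params$xi
}

#' Fit the log-PTT regression model
#'
#' Ordinary least squares of blood pressure on `ln(PTT)`:
#' `P = K1 * ln(PTT) + K2`.
#'
#' @param ptt Transit times (s), at least two distinct values.
#' @param bp Matching pressures (mmHg).
#' @return A [regression_coeffs()].
#' @export
regression_fit <- function(ptt, bp) {
  if (length(ptt) != length(bp)) {
    abort_calibration("'ptt' and 'bp' must have equal length")
  }
  if (length(ptt) < 2L || length(unique(ptt)) < 2L) {
    abort_calibration("need >= 2 pairs with distinct ptt to fit K1, K2")
  }
  if (any(ptt <= 0)) abort_calibration("'ptt' must be > 0")
  x <- log(ptt)
  K1 <- sum((x - mean(x)) * (bp - mean(bp))) / sum((x - mean(x))^2)
  K2 <- mean(bp) - K1 * mean(x)
  regression_coeffs(K1, K2)
}

#' Predict pressure from the log-PTT regression model
#'
#' @param coeffs A [regression_coeffs()].
#' @param ptt Transit time(s) (s).
#' @return Pressure (mmHg).
#' @export
regression_predict <- function(coeffs, ptt) {
  stopifnot(inherits(coeffs, "regression_coeffs"))
  if (!is.numeric(ptt) || any(!is.finite(ptt)) || any(ptt <= 0)) {
    abort_invalid("'ptt' must be > 0")
  }
  coeffs$K1 * log(ptt) + coeffs$K2
}

#' Pulse pressure from wave speed and diameter excursion
#'
#' Bramwell-Hill form of the pulse pressure:
#' `dP = rho * PWV^2 * (2 * dD/Dd + (dD/Dd)^2)`, evaluated in pascal and
#' returned in mmHg.
#'
#' @param state An [arterial_state()] carrying `deltaD` and `Dd`.
#' @param pwv Wave speed (m/s), non-negative.
#' @return Pulse pressure (mmHg).
#' @export
pulse_pressure <- function(state, pwv) {
  stopifnot(inherits(state, "arterial_state"))
  if (state$Dd <= 0) abort_invalid("'Dd' must be > 0")
  if (!is.numeric(pwv) || any(pwv < 0)) abort_invalid("'pwv' must be >= 0")
  r <- state$deltaD / state$Dd
  pa_to_mmhg(state$rho_blood * pwv^2 * (2 * r + r^2))
}

#' Mean arterial pressure from the P-beta model
#'
#' `MAP = 2 * rho * PWV^2 * Dd / (beta * D)` (pascal, returned in mmHg),
#' with `beta` the per-subject local stiffness constant. With the default
#' `D = Dd` the geometric factor is neutral and the relation reduces to
#' `2 * rho * PWV^2 / beta`.
#'
#' @param state An [arterial_state()].
#' @param params A [stiffness_params()] with `beta` set, or a single
#'   numeric beta value.
#' @param pwv Wave speed (m/s), non-negative.
#' @return Mean arterial pressure (mmHg).
#' @export
map_p_beta <- function(state, params, pwv) {
  stopifnot(inherits(state, "arterial_state"))
  beta <- if (inherits(params, "stiffness_params")) params$beta else params
  if (!is.numeric(beta) || is.na(beta) || beta <= 0) {
    abort_invalid("'beta' must be > 0")
  }
  if (state$D <= 0) abort_invalid("'D' must be > 0")
  if (!is.numeric(pwv) || any(pwv < 0)) abort_invalid("'pwv' must be >= 0")
  pa_to_mmhg(2 * state$rho_blood * pwv^2 * state$Dd / (beta * state$D))
}

#' One-point calibration of the stiffness constant beta
#'
#' Inverts the P-beta relation at a single reference reading:
#' returns the `beta` for which [map_p_beta()] reproduces `map_ref`
#' exactly at `pwv_cal`.
#'
#' @param state An [arterial_state()].
#' @param pwv_cal Wave speed at calibration (m/s).
#' @param map_ref Reference mean arterial pressure (mmHg).
#' @return The calibrated beta (dimensionless).
#' @export
beta_calibrate <- function(state, pwv_cal, map_ref) {
  stopifnot(inherits(state, "arterial_state"))
  if (!is.numeric(pwv_cal) || pwv_cal <= 0 || !is.numeric(map_ref) ||
      map_ref <= 0) {
    abort_calibration("'pwv_cal' and 'map_ref' must be > 0")
  }
  2 * state$rho_blood * pwv_cal^2 * state$Dd /
    (state$D * mmhg_to_pa(map_ref))
}

#' Track systolic and diastolic pressure from mean pressure
#'
#' Decomposes a mean arterial pressure into systolic/diastolic values with
#' the tracking coefficient `k`:
#' `DBP = MAP * k`, `SBP = MAP + (1 - k) * DBP`.
#' The pulse pressure `pp` is carried into the returned estimate for
#' reporting but is not consumed by this default decomposition. Setting
#' `variant = "pp"` substitutes `SBP = MAP + (1 - k) * PP`, a non-default
#' alternative that does consume the measured pulse pressure.
#'
#' @param map Mean arterial pressure (mmHg), positive.
#' @param pp Pulse pressure (mmHg) to report (and to consume when
#'   `variant = "pp"`).
#' @param k Tracking coefficient in (0, 1]; default 0.76.
#' @param variant `"printed"` (default) or `"pp"`.
#' @param method Method label stored on the returned estimate.
#' @return A [bp_estimate()].
#' @examples
#' track_sbp_dbp(100)  # DBP 76, SBP 118.24
#' @export
track_sbp_dbp <- function(map, pp = NA_real_, k = 0.76,
                          variant = c("printed", "pp"),
                          method = "p_beta") {
  variant <- match.arg(variant)
  check_scalar(map, "map")
  check_scalar(k, "k")
  if (k > 1) abort_invalid("'k' must be in (0, 1]")
  dbp <- map * k
  sbp <- if (variant == "printed") {
    map + (1 - k) * dbp
  } else {
    if (!is.finite(pp)) abort_invalid("variant 'pp' needs a finite pulse pressure")
    map + (1 - k) * pp
  }
  bp_estimate(sbp = sbp, dbp = dbp, map = map, pp = pp, method = method)
}
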