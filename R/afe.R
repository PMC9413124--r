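# Forward model of the analog front end: parasitic-capacitance high-pass,
# DC offset, gain stage, second-order Sallen-Key low-pass; each stage
# discretized by the bilinear transform.

#' Analog front-end component values
#'
#' Defaults are back-solved from the design targets: piezo parasitic
#' capacitance 8000 pF with a 20 MOhm load (first-order high-pass at
#' ~0.995 Hz), half-supply DC offset (R1 = R2), a flat gain of 18, and a
#' Sallen-Key low-pass with equal R and C pairs placing the cutoff at
#' 10.6 Hz. Only the targets are published for the device; the remaining
#' component values here realize them.
#'
#' @param R1,R2 Load/offset resistors (Ohm).
#' @param R3,R4 Gain-stage resistors (Ohm); `C1` sets the gain-stage AC
#'   coupling. The model applies the flat passband gain `gain` rather than
#'   the full frequency-dependent gain expression.
#' @param R5,R6 Sallen-Key resistors (Ohm); must be equal.
#' @param C1,C2,C3 Capacitors (F); `C2` and `C3` must be equal.
#' @param Cp Piezo parasitic capacitance (F); default 8e-9 (8000 pF).
#' @param Vcc Supply voltage (V).
#' @param gain Linear passband amplification (default 18).
#' @return An object of class `afe_params`.
#' @export
afe_params <- function(R1 = 20e6, R2 = 20e6, R3 = 1e3, R4 = 17e3,
                       R5 = 1 / (2 * pi * 10.6 * 1e-7),
                       R6 = 1 / (2 * pi * 10.6 * 1e-7),
                       C1 = 4.7e-4, C2 = 1e-7, C3 = 1e-7,
                       Cp = 8e-9, Vcc = 3.3, gain = 18) {
  vals <- list(R1 = R1, R2 = R2, R3 = R3, R4 = R4, R5 = R5, R6 = R6,
               C1 = C1, C2 = C2, C3 = C3, Cp = Cp, Vcc = Vcc, gain = gain)
  for (nm in names(vals)) check_scalar(vals[[nm]], nm)
  if (!isTRUE(all.equal(R5, R6))) abort_invalid("R5 and R6 must be equal")
  if (!isTRUE(all.equal(C2, C3))) abort_invalid("C2 and C3 must be equal")
  structure(vals, class = "afe_params")
}

#' High-pass cutoff from the parasitic capacitance
#'
#' `f = 1 / (2 * pi * R1 * Cp)`: the piezo's parasitic capacitance against
#' the external load resistor forms a first-order high-pass.
#'
#' @param R1 Load resistance (Ohm).
#' @param Cp Parasitic capacitance (F).
#' @return Cutoff frequency (Hz).
#' @export
hp_cutoff <- function(R1, Cp) {
  check_scalar(R1, "R1")
  check_scalar(Cp, "Cp")
  1 / (2 * pi * R1 * Cp)
}

#' DC offset stage
#'
#' Adds the divider offset `Vcc * R1 / (R1 + R2)` to the piezo voltage;
#' with `R1 = R2` the offset is half supply.
#'
#' @param vp A [pulse_signal()] (V) or numeric vector.
#' @param Vcc Supply voltage (V).
#' @param R1,R2 Divider resistors (Ohm).
#' @return Offset signal, same type as `vp`.
#' @export
dc_offset <- function(vp, Vcc = 3.3, R1 = 20e6, R2 = 20e6) {
  check_scalar(R1, "R1")
  check_scalar(R2, "R2")
  off <- Vcc * R1 / (R1 + R2)
  if (inherits(vp, "pulse_signal")) {
    signal_with(vp, vp$samples + off, unit = "V")
  } else {
    vp + off
  }
}

#' Sallen-Key low-pass cutoff
#'
#' `fc = 1 / (2 * pi * sqrt(R5 * C2 * R6 * C3))`.
#'
#' @param R5,R6 Resistances (Ohm).
#' @param C2,C3 Capacitances (F).
#' @return Cutoff frequency (Hz).
#' @export
sallen_key_cutoff <- function(R5, R6, C2, C3) {
  for (v in list(R5, R6, C2, C3)) {
    if (!is.numeric(v) || v <= 0) abort_invalid("all components must be > 0")
  }
  1 / (2 * pi * sqrt(R5 * C2 * R6 * C3))
}

# Digital coefficients for the two IIR stages.
afe_hp_coeffs <- function(params, fs) {
  wc <- 2 * pi * hp_cutoff(params$R1, params$Cp)
  bilinear_biquad(B = c(0, 1, 0), A = c(wc, 1, 0), fs)
}

afe_lp_coeffs <- function(params, fs) {
  # Sallen-Key transfer function: w0^2 / (s^2 + s*(1/(R6 C2) + 1/(R5 C2)) + w0^2)
  w0sq <- 1 / (params$R5 * params$C2 * params$R6 * params$C3)
  a1 <- 1 / (params$R6 * params$C2) + 1 / (params$R5 * params$C2)
  bilinear_biquad(B = c(w0sq, 0, 0), A = c(w0sq, a1, 1), fs)
}

# Analog magnitude responses (for verification against the discretized
# stages).
afe_lp_analog_mag <- function(params, f) {
  w0sq <- 1 / (params$R5 * params$C2 * params$R6 * params$C3)
  a1 <- 1 / (params$R6 * params$C2) + 1 / (params$R5 * params$C2)
  s <- 2i * pi * f
  Mod(w0sq / (s^2 + a1 * s + w0sq))
}

afe_hp_analog_mag <- function(params, f) {
  wc <- 2 * pi * hp_cutoff(params$R1, params$Cp)
  s <- 2i * pi * f
  Mod(s / (s + wc))
}

#' Apply the analog front end to a sensor voltage
#'
#' In order: first-order high-pass at [hp_cutoff()], flat gain (the
#' gain-stage DC gain is unity, so the divider offset passes unscaled),
#' DC offset to mid-rail, second-order Sallen-Key low-pass, and clipping
#' to the supply rails `[0, Vcc]`. The two IIR stages are discretized by
#' the bilinear transform at `fs` without pre-warping (the corner
#' frequencies are orders of magnitude below `fs / 2`).
#'
#' @param signal A [pulse_signal()] of sensor voltage (V).
#' @param params An [afe_params()].
#' @param fs Sampling rate (Hz); defaults to the signal's rate. Must
#'   exceed four times the low-pass cutoff.
#' @return The conditioned [pulse_signal()] (V), clipped to the rails;
#'   saturation triggers a warning.
#' @export
afe_apply <- function(signal, params = afe_params(), fs = signal$fs) {
  stopifnot(inherits(signal, "pulse_signal"), inherits(params, "afe_params"))
  fc <- sallen_key_cutoff(params$R5, params$R6, params$C2, params$C3)
  if (fs <= 4 * fc) {
    abort_config(sprintf("fs = %g Hz too low for LPF cutoff %.3g Hz", fs, fc))
  }
  hp <- afe_hp_coeffs(params, fs)
  lp <- afe_lp_coeffs(params, fs)
  y <- iir_apply(signal$samples, hp$b, hp$a)
  y <- params$gain * y + params$Vcc * params$R1 / (params$R1 + params$R2)
  y <- iir_apply(y, lp$b, lp$a)
  clipped <- y < 0 | y > params$Vcc
  if (any(clipped)) {
    warning(sprintf("AFE saturation: %d of %d samples clipped to the rails",
                    sum(clipped), length(y)), call. = FALSE)
    y <- pmin(pmax(y, 0), params$Vcc)
  }
  signal_with(signal, y, unit = "V")
}
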