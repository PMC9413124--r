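# PPG feature extraction and arterial-dimension estimation: per-beat IH/IL,
# the PPG intensity ratio (PIR), normalized PPG, diameter excursion via
# Beer-Lambert inversion, and the diameter regression model against a
# reference (ultrasound-surrogate) dimension table.

#' Detect cardiac cycles on a PPG channel
#'
#' The PPG dips at systole (more blood, more absorption), so beats are
#' detected on the negated band-pass-filtered signal with the standard
#' dynamic-threshold detector. The returned foot times segment the raw PPG
#' into cardiac-cycle windows.
#'
#' @param ppg A raw [pulse_signal()] with role `"ppg"`.
#' @return A [beat_features()].
#' @export
detect_ppg_beats <- function(ppg) {
  stopifnot(inherits(ppg, "pulse_signal"))
  filt <- bpf_apply(signal_with(ppg, -ppg$samples))
  trim_beat_edges(detect_beats(filt), signal_duration(ppg))
}

#' Per-beat PPG intensity extrema and PIR
#'
#' For each cardiac cycle (delimited by consecutive beat feet), takes the
#' maximum (`ih`) and minimum (`il`) of the raw, DC-containing PPG, each
#' refined by a three-point parabolic fit so the sampled extremum tracks
#' the underlying continuous one. Cycles containing saturated samples
#' (0 or full-scale 18-bit counts) are flagged invalid.
#'
#' @param ppg A raw [pulse_signal()] in ADC counts.
#' @param beats Optional [beat_features()] delimiting cycles (e.g. mapped
#'   from the piezo timing); defaults to self-segmentation via
#'   [detect_ppg_beats()].
#' @return An object of class `pir_measurement`: a list with the per-beat
#'   `ih`, `il`, `dc` (cycle mean), `pir`, `valid` flags, and the session
#'   medians `pir_median` and `ppg_norm` (quotient reading).
#' @export
extract_ih_il <- function(ppg, beats = NULL) {
  stopifnot(inherits(ppg, "pulse_signal"))
  if (any(ppg$samples < 0)) abort_data("PPG intensities must be non-negative")
  if (is.null(beats)) beats <- detect_ppg_beats(ppg)
  ft <- beats$foot_times[beats$valid]
  if (length(ft) < 2L) {
    return(structure(list(ih = numeric(0), il = numeric(0), dc = numeric(0),
                          pir = numeric(0), valid = logical(0),
                          pir_median = NA_real_, ppg_norm = NA_real_),
                     class = "pir_measurement"))
  }
  x <- ppg$samples
  fs <- ppg$fs
  n <- length(x)
  refine <- function(idx, sign) {
    if (idx <= 1L || idx >= n) return(x[idx])
    off <- parabolic_offset(sign * x, idx)
    # value at the parabola vertex
    d <- (x[idx + 1] - x[idx - 1]) / 2
    x[idx] + d * off + 0.5 * (x[idx + 1] - 2 * x[idx] + x[idx - 1]) * off^2
  }
  nb <- length(ft) - 1L
  ih <- il <- dc <- numeric(nb)
  valid <- logical(nb)
  for (b in seq_len(nb)) {
    i1 <- max(1L, floor(ft[b] * fs) + 1L)
    i2 <- min(n, ceiling(ft[b + 1] * fs) + 1L)
    w <- x[i1:i2]
    imax <- i1 - 1L + which.max(w)
    imin <- i1 - 1L + which.min(w)
    ih[b] <- refine(imax, +1)
    il[b] <- refine(imin, -1)
    dc[b] <- mean(w)
    valid[b] <- all(w > 0 & w < ADC_PPG_MAX) && ih[b] > il[b] && il[b] > 0
  }
  pir <- ih / il
  ok <- valid & is.finite(pir) & pir >= 1
  pir_median <- if (any(ok)) stats::median(pir[ok]) else NA_real_
  ppg_norm_med <- if (any(ok)) {
    stats::median(ppg_norm(ih[ok] - il[ok], dc[ok]))
  } else NA_real_
  structure(
    list(ih = ih, il = il, dc = dc, pir = pir, valid = valid,
         pir_median = pir_median, ppg_norm = ppg_norm_med),
    class = "pir_measurement"
  )
}

#' @export
print.pir_measurement <- function(x, ...) {
  cat(sprintf("<pir_measurement: %d cycles (%d valid), PIR median %.4f>\n",
              length(x$pir), sum(x$valid), x$pir_median))
  invisible(x)
}

#' Normalized PPG
#'
#' The default `"quotient"` reading is `ln(AC) / ln(DC)`; the alternative
#' `"ratio"` reading `ln(AC / DC)` is provided behind a switch (it goes
#' negative whenever AC < DC, which breaks a monotone diameter mapping, and
#' is therefore not the default).
#'
#' @param ac_amplitude Per-beat AC amplitude (`ih - il`), positive.
#' @param dc_level Per-beat DC level (cycle mean), > 1 count for the
#'   quotient reading.
#' @param reading `"quotient"` (default) or `"ratio"`.
#' @return Dimensionless normalized PPG.
#' @export
ppg_norm <- function(ac_amplitude, dc_level,
                     reading = c("quotient", "ratio")) {
  reading <- match.arg(reading)
  if (any(ac_amplitude <= 0)) abort_data("'ac_amplitude' must be > 0")
  if (reading == "quotient") {
    if (any(dc_level <= 1)) {
      abort_data("'dc_level' must exceed 1 for the quotient normalization")
    }
    log(ac_amplitude) / log(dc_level)
  } else {
    if (any(dc_level <= 0)) abort_data("'dc_level' must be > 0")
    log(ac_amplitude / dc_level)
  }
}

#' Diameter excursion from the PPG intensity ratio
#'
#' Beer-Lambert inversion: `deltaD = ln(PIR) / alpha`.
#'
#' @param pir_value PIR (`IH / IL`), >= 1.
#' @param alpha Arterial absorbance coefficient (1/m).
#' @return Diameter excursion (m).
#' @export
delta_d_from_pir <- function(pir_value, alpha) {
  check_scalar(alpha, "alpha")
  if (any(!is.finite(pir_value)) || any(pir_value < 1)) {
    abort_data("'pir_value' must be >= 1 (negative excursion implied)")
  }
  log(pir_value) / alpha
}

#' Calibrate the arterial absorbance coefficient
#'
#' Inverts the Beer-Lambert excursion relation at one reference dimension:
#' `alpha = ln(PIR) / deltaD_ref`, the exact round-trip partner of
#' [delta_d_from_pir()].
#'
#' @param pir_cal Calibration PIR, > 1.
#' @param delta_d_ref Reference diameter excursion (m), > 0.
#' @return Absorbance coefficient alpha (1/m).
#' @export
alpha_calibrate <- function(pir_cal, delta_d_ref) {
  if (!is.numeric(pir_cal) || pir_cal <= 1) {
    abort_calibration("'pir_cal' must be > 1")
  }
  if (!is.numeric(delta_d_ref) || delta_d_ref <= 0) {
    abort_calibration("'delta_d_ref' must be > 0")
  }
  log(pir_cal) / delta_d_ref
}

#' Fit the diameter regression model
#'
#' Least-squares line mapping normalized PPG to end-diastolic diameter,
#' standing in for the regression of ultrasound-measured dimensions on the
#' quantized PPG. Predictions outside the fitted `ppg_norm` range are
#' flagged as extrapolation.
#'
#' @param ppg_norm Normalized PPG values (>= 3, spanning a nonzero range).
#' @param dd_ref Reference end-diastolic diameters (m).
#' @param alpha Optional absorbance coefficient stored with the model.
#' @return An object of class `diameter_model` with `slope`, `intercept`,
#'   `alpha`, `fit_r2` and the fitted `range`.
#' @export
fit_diameter_model <- function(ppg_norm, dd_ref, alpha = NA_real_) {
  if (length(ppg_norm) != length(dd_ref)) {
    abort_calibration("'ppg_norm' and 'dd_ref' must have equal length")
  }
  if (length(ppg_norm) < 3L) abort_calibration("need >= 3 observations")
  if (diff(range(ppg_norm)) <= 0) {
    abort_calibration("'ppg_norm' observations span a degenerate range")
  }
  x <- ppg_norm
  y <- dd_ref
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  fitted <- slope * x + intercept
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(slope = slope, intercept = intercept, alpha = alpha,
         fit_r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         range = range(x)),
    class = "diameter_model"
  )
}

#' Predict end-diastolic diameter from normalized PPG
#'
#' @param model A [fit_diameter_model()] fit.
#' @param ppg_norm Normalized PPG value(s).
#' @return Predicted diameters (m) with attribute `extrapolated`: logical,
#'   `TRUE` where the input lies outside the fitted range.
#' @export
predict_dd <- function(model, ppg_norm) {
  stopifnot(inherits(model, "diameter_model"))
  out <- model$slope * ppg_norm + model$intercept
  extrap <- ppg_norm < model$range[1] | ppg_norm > model$range[2]
  if (any(extrap)) {
    warning("diameter model applied outside its fitted ppg_norm range",
            call. = FALSE)
  }
  attr(out, "extrapolated") <- extrap
  out
}
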