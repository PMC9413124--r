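# Orchestration: per-subject calibration (one reference BP reading plus
# reference arterial dimensions) and per-session estimation by either the
# log-PTT regression arm or the P-beta arm.

#' One measurement session
#'
#' @param subject_id Subject label.
#' @param signals Named list with `piezo_proximal`, `piezo_distal` and
#'   `ppg` [pulse_signal()] channels.
#' @param duration Record length (s), >= 10.
#' @param sensor_distance Inter-sensor distance (m).
#' @param label Session label.
#' @return An object of class `session_record`.
#' @export
session_record <- function(subject_id, signals, duration, sensor_distance,
                           label = "s1") {
  need <- c("piezo_proximal", "piezo_distal", "ppg")
  missing <- setdiff(need, names(signals))
  if (length(missing)) {
    abort_format(paste("session is missing channel(s):",
                       paste(missing, collapse = ", ")))
  }
  for (nm in need) stopifnot(inherits(signals[[nm]], "pulse_signal"))
  if (duration < 10) abort_invalid("'duration' must be >= 10 s")
  check_scalar(sensor_distance, "sensor_distance")
  structure(
    list(subject_id = subject_id, signals = signals[need],
         duration = duration, sensor_distance = sensor_distance,
         label = label),
    class = "session_record"
  )
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record %s/%s: %.0f s, piezo @ %g Hz, ppg @ %g Hz>\n",
              x$subject_id, x$label, x$duration,
              x$signals$piezo_proximal$fs, x$signals$ppg$fs))
  invisible(x)
}

#' Per-subject calibration state
#'
#' @param subject_id Subject the state belongs to.
#' @param beta Calibrated stiffness constant (P-beta arm).
#' @param alpha Calibrated absorbance coefficient (1/m).
#' @param k Tracking coefficient (from the reference reading,
#'   `ref_dbp / ref_map`).
#' @param dd_ref Reference end-diastolic diameter (m).
#' @param delta_d_ref Reference diameter excursion (m).
#' @param ref_bp Named numeric `c(sbp, dbp, map)` (mmHg).
#' @param anchors Data frame of `(ptt, sbp, dbp, map)` anchor readings
#'   accumulated for the regression arm.
#' @param regression Optional per-measure list of [regression_coeffs()]
#'   (set by [fit_regression_arm()]).
#' @param diameter_model Optional [fit_diameter_model()] fit.
#' @param calibrated_at Session label of the calibration session.
#' @return An object of class `calibration_state`.
#' @export
calibration_state <- function(subject_id, beta = NA_real_, alpha = NA_real_,
                              k = 0.76, dd_ref = NA_real_,
                              delta_d_ref = NA_real_, ref_bp = NULL,
                              anchors = NULL, regression = NULL,
                              diameter_model = NULL, calibrated_at = NA) {
  if (!is.na(beta) && beta <= 0) abort_invalid("'beta' must be > 0")
  if (!is.na(alpha) && alpha <= 0) abort_invalid("'alpha' must be > 0")
  structure(
    list(subject_id = subject_id, beta = beta, alpha = alpha, k = k,
         dd_ref = dd_ref, delta_d_ref = delta_d_ref, ref_bp = ref_bp,
         anchors = anchors, regression = regression,
         diameter_model = diameter_model, calibrated_at = calibrated_at),
    class = "calibration_state"
  )
}

#' @export
print.calibration_state <- function(x, ...) {
  cat(sprintf("<calibration_state %s: beta %.3g, alpha %.3g /m, k %.3f, %d anchor(s)>\n",
              x$subject_id, x$beta, x$alpha, x$k,
              if (is.null(x$anchors)) 0L else nrow(x$anchors)))
  invisible(x)
}

# ---- signal processing shared by calibrate/estimate ----------------------

# Piezo chain: decimate both channels to the working rate, band-pass,
# detect beats, pair, and measure PTT/PWV.
process_piezo <- function(record, config = default_config()) {
  dsp <- config$dsp
  pre <- function(role) {
    sig <- decimate(record$signals[[role]], dsp$fs_work)
    bpf_apply(sig, design_bpf(dsp$fs_work, dsp$f_hp, dsp$f_lp))
  }
  sig_prox <- pre("piezo_proximal")
  sig_dist <- pre("piezo_distal")
  prox <- trim_beat_edges(detect_beats(sig_prox, decay_s = dsp$decay_s,
                                       threshold_frac = dsp$threshold_frac,
                                       refractory_s = dsp$refractory_s),
                          signal_duration(sig_prox))
  dist <- trim_beat_edges(detect_beats(sig_dist, decay_s = dsp$decay_s,
                                       threshold_frac = dsp$threshold_frac,
                                       refractory_s = dsp$refractory_s),
                          signal_duration(sig_dist))
  if (isTRUE(dsp$template_refine)) {
    refined <- refine_feet_template(sig_prox, sig_dist, prox, dist,
                                    win_s = dsp$refine_win_s,
                                    max_lag_s = dsp$refine_maxlag_s)
    prox <- refined$proximal
    dist <- refined$distal
  }
  ptt <- pair_and_ptt(prox, dist, record$sensor_distance,
                      max_lag_s = dsp$pair_window_s)
  list(proximal = prox, distal = dist, ptt = ptt)
}

process_ppg <- function(record, config = default_config()) {
  extract_ih_il(record$signals$ppg)
}

# Session quality gates: enough paired beats, plausible rhythm, and (when a
# PIR measurement is involved) a usable PIR. Returns NULL when all pass.
quality_gate <- function(piezo, pir = NULL, config = default_config()) {
  gates <- config$quality
  if (piezo$ptt$n_beats_used < gates$min_paired_beats) {
    return(sprintf("only %d paired beats (< %d)", piezo$ptt$n_beats_used,
                   gates$min_paired_beats))
  }
  ibi <- diff(piezo$proximal$foot_times[piezo$proximal$valid])
  # a dropped beat leaves a gap near a multiple of the underlying period;
  # the rhythm-regularity check is computed over non-gap intervals
  ibi <- ibi[ibi <= 1.5 * stats::median(ibi)]
  if (length(ibi) >= 2L) {
    cv <- stats::sd(ibi) / mean(ibi)
    if (cv >= gates$max_interval_cv) {
      return(sprintf("beat-interval CV %.2f >= %.2f", cv,
                     gates$max_interval_cv))
    }
  }
  if (!is.null(pir) &&
      (!is.finite(pir$pir_median) || pir$pir_median < gates$min_pir)) {
    return(sprintf("PIR median %.4f degenerate (< %.4f)", pir$pir_median,
                   gates$min_pir))
  }
  NULL
}

# ---- calibration ---------------------------------------------------------

#' Calibrate a subject from one session and a reference reading
#'
#' Measures PTT/PWV and PIR from the session, then fits the per-subject
#' constants: the absorbance coefficient `alpha` against the reference
#' diameter excursion, the stiffness constant `beta` against the reference
#' mean pressure (one-point calibration), and the tracking coefficient
#' `k = ref_dbp / ref_map`. The `(PTT, BP)` reading is stored as an anchor
#' for the regression arm, which needs anchors from at least two sessions
#' ([fit_regression_arm()]).
#'
#' @param record A [session_record()].
#' @param ref_bp Named numeric with `sbp`, `dbp`, `map` (mmHg).
#' @param ref_dims One row of the reference dimension table for this
#'   subject (`dd_mm`, `delta_d_mm`), or a named numeric.
#' @param config Pipeline configuration ([default_config()]).
#' @return A [calibration_state()].
#' @export
calibrate <- function(record, ref_bp, ref_dims, config = default_config()) {
  stopifnot(inherits(record, "session_record"))
  ref_bp <- unlist(ref_bp)[c("sbp", "dbp", "map")]
  if (anyNA(ref_bp) || any(ref_bp <= 0)) {
    abort_calibration("'ref_bp' must provide positive sbp, dbp and map")
  }
  if (is.data.frame(ref_dims)) {
    if ("subject_id" %in% names(ref_dims)) {
      ref_dims <- ref_dims[ref_dims$subject_id == record$subject_id, ]
      if (nrow(ref_dims) != 1L) {
        abort_calibration(sprintf("no unique reference dimensions for '%s'",
                                  record$subject_id))
      }
    }
    ref_dims <- unlist(ref_dims[1, c("dd_mm", "delta_d_mm")])
  } else {
    ref_dims <- unlist(ref_dims)[c("dd_mm", "delta_d_mm")]
  }
  dd_ref <- ref_dims[["dd_mm"]] * 1e-3
  delta_d_ref <- ref_dims[["delta_d_mm"]] * 1e-3
  piezo <- process_piezo(record, config)
  pir <- process_ppg(record, config)
  reason <- quality_gate(piezo, pir, config)
  if (!is.null(reason)) {
    abort_calibration(paste("calibration rejected:", reason))
  }
  alpha <- alpha_calibrate(pir$pir_median, delta_d_ref)
  state <- arterial_state(Dd = dd_ref, deltaD = delta_d_ref, h = 3e-4,
                          rho_blood = config$rho_blood)
  beta <- beta_calibrate(state, piezo$ptt$pwv, ref_bp[["map"]])
  calibration_state(
    subject_id = record$subject_id, beta = beta, alpha = alpha,
    k = ref_bp[["dbp"]] / ref_bp[["map"]], dd_ref = dd_ref,
    delta_d_ref = delta_d_ref, ref_bp = ref_bp,
    anchors = data.frame(ptt = piezo$ptt$ptt_median, sbp = ref_bp[["sbp"]],
                         dbp = ref_bp[["dbp"]], map = ref_bp[["map"]]),
    calibrated_at = record$label
  )
}

#' Fit the regression arm from multiple calibration states
#'
#' Pools the `(PTT, BP)` anchors of two or more calibrations of the same
#' subject and fits `P = K1 * ln(PTT) + K2` separately for systolic,
#' diastolic and mean pressure. Returns the most recent state with the
#' fitted coefficients attached.
#'
#' @param cals List of [calibration_state()] for one subject.
#' @return A [calibration_state()] with `regression` set.
#' @export
fit_regression_arm <- function(cals) {
  if (inherits(cals, "calibration_state")) cals <- list(cals)
  ids <- unique(vapply(cals, `[[`, "", "subject_id"))
  if (length(ids) != 1L) {
    abort_usage("all calibration states must belong to the same subject")
  }
  anchors <- do.call(rbind, lapply(cals, `[[`, "anchors"))
  if (is.null(anchors) || nrow(anchors) < 2L) {
    abort_calibration("regression arm needs anchors from >= 2 sessions")
  }
  out <- cals[[length(cals)]]
  out$anchors <- anchors
  out$regression <- list(
    sbp = regression_fit(anchors$ptt, anchors$sbp),
    dbp = regression_fit(anchors$ptt, anchors$dbp),
    map = regression_fit(anchors$ptt, anchors$map)
  )
  out
}

#' Fit a pooled (cohort-level) log-PTT regression
#'
#' Pools the `(PTT, BP)` anchors of many subjects' calibrations and fits a
#' single `P = K1 ln(PTT) + K2` per pressure — the generalized PTT-to-BP
#' curve that per-subject arterial heterogeneity degrades. Used as the
#' comparison arm for the stiffness-calibrated P-beta model.
#'
#' @param cals List of [calibration_state()] (any subjects).
#' @return Named list of [regression_coeffs()] for `sbp`, `dbp`, `map`.
#' @export
fit_regression_pooled <- function(cals) {
  anchors <- do.call(rbind, lapply(cals, `[[`, "anchors"))
  if (is.null(anchors) || nrow(anchors) < 2L) {
    abort_calibration("pooled regression needs >= 2 anchor readings")
  }
  list(sbp = regression_fit(anchors$ptt, anchors$sbp),
       dbp = regression_fit(anchors$ptt, anchors$dbp),
       map = regression_fit(anchors$ptt, anchors$map))
}

#' Ground-truth calibration of a simulated subject
#'
#' Builds the calibration state directly from a [subject_profile()]'s
#' generator truth (exact beta at the baseline pressure, exact alpha, k and
#' dimensions), bypassing signal processing. Used to isolate measurement
#' error from calibration error in round-trip checks.
#'
#' @param profile A [subject_profile()].
#' @return A [calibration_state()].
#' @export
true_calibration <- function(profile) {
  stopifnot(inherits(profile, "subject_profile"))
  calibration_state(
    subject_id = profile$subject_id,
    beta = profile$true_beta,
    alpha = profile$optics$alpha,
    k = profile$stiffness$k,
    dd_ref = profile$arterial$Dd,
    delta_d_ref = profile$arterial$deltaD,
    ref_bp = c(sbp = profile$true_sbp, dbp = profile$true_dbp,
               map = profile$true_map),
    calibrated_at = "truth"
  )
}

# ---- estimation ----------------------------------------------------------

#' Estimate blood pressure for a session
#'
#' The regression arm reads only the piezo channels: PTT median ->
#' `P = K1 ln(PTT) + K2` per pressure. The P-beta arm reads piezo and PPG:
#' PTT median -> PWV; PIR -> diameter excursion (via the calibrated alpha)
#' and end-diastolic diameter (via the diameter model when present,
#' otherwise the reference dimension); then pulse pressure, mean pressure
#' from the P-beta relation, and systolic/diastolic tracking with the
#' calibrated `k`.
#'
#' @param record A [session_record()].
#' @param cal A [calibration_state()] for the same subject.
#' @param method `"p_beta"` (default) or `"regression"`.
#' @param config Pipeline configuration.
#' @return A [bp_estimate()]; the measured intermediates (ptt, pwv, pir,
#'   delta_d, dd) are attached as attribute `"details"`. A session failing
#'   the quality gates returns an estimate flagged invalid.
#' @export
estimate <- function(record, cal, method = c("p_beta", "regression"),
                     config = default_config()) {
  stopifnot(inherits(record, "session_record"),
            inherits(cal, "calibration_state"))
  method <- match.arg(method)
  if (!identical(record$subject_id, cal$subject_id)) {
    abort_usage(sprintf(
      "calibration for '%s' cannot be used on a session of '%s'",
      cal$subject_id, record$subject_id))
  }
  piezo <- process_piezo(record, config)
  details <- list(ptt = piezo$ptt$ptt_median, pwv = piezo$ptt$pwv,
                  n_beats = piezo$ptt$n_beats_used)

  if (method == "regression") {
    if (is.null(cal$regression)) {
      abort_calibration("regression coefficients not fitted; run fit_regression_arm()")
    }
    gate <- quality_gate(piezo, config = config)
    ptt <- piezo$ptt$ptt_median
    est <- bp_estimate(
      sbp = regression_predict(cal$regression$sbp, ptt),
      dbp = regression_predict(cal$regression$dbp, ptt),
      map = regression_predict(cal$regression$map, ptt),
      method = "regression"
    )
    est$valid <- est$valid && is.null(gate)
    attr(est, "details") <- c(details, list(gate = gate %||% "pass"))
    return(est)
  }

  pir <- process_ppg(record, config)
  gate <- quality_gate(piezo, pir, config)
  delta_d <- if (is.finite(pir$pir_median) && pir$pir_median >= 1) {
    delta_d_from_pir(pir$pir_median, cal$alpha)
  } else NA_real_
  dd <- if (!is.null(cal$diameter_model) && is.finite(pir$ppg_norm)) {
    suppressWarnings(as.numeric(predict_dd(cal$diameter_model, pir$ppg_norm)))
  } else cal$dd_ref
  # excursion capped at the physiological 10% bound the diameter model assumes
  delta_d_use <- if (is.finite(delta_d)) min(delta_d, 0.099 * dd) else 0
  state <- arterial_state(Dd = dd, deltaD = delta_d_use,
                          h = 3e-4, rho_blood = config$rho_blood)
  map <- map_p_beta(state, cal$beta, piezo$ptt$pwv)
  pp <- pulse_pressure(state, piezo$ptt$pwv)
  est <- track_sbp_dbp(map, pp = pp, k = cal$k,
                       variant = config$tracking_variant)
  est$valid <- est$valid && is.null(gate)
  details <- c(details, list(pir = pir$pir_median, ppg_norm = pir$ppg_norm,
                             delta_d = delta_d, dd = dd,
                             gate = gate %||% "pass"))
  attr(est, "details") <- details
  est
}

# ---- cohort driver -------------------------------------------------------

#' Simulate and evaluate a full cohort
#'
#' Generates `n_subjects` subjects with `n_sessions` sessions each, then
#' runs both estimation arms: the P-beta arm is calibrated on session 1
#' (one-point calibration) and evaluated on sessions 2..n; the regression
#' arm takes its two anchors from sessions 1-2 and is evaluated on
#' sessions 3..n. A cohort-level diameter model is fitted from the
#' calibration sessions' `(ppg_norm, dd_ref)` pairs and attached to every
#' subject's calibration.
#'
#' @param n_subjects,n_sessions Cohort shape (regression arm needs
#'   `n_sessions >= 3`).
#' @param seed Master RNG seed.
#' @param snr_db Additive-noise SNR (dB).
#' @param duration Session length (s).
#' @param session_bp_sd Visit-to-visit MAP standard deviation (mmHg).
#' @param methods Arms to run.
#' @param regression_scope `"pooled"` (one cohort-level curve, the
#'   generalized PTT-to-BP regression the P-beta model is compared
#'   against) or `"subject"` (per-subject two-anchor calibration).
#' @param ranges Cohort parameter ranges.
#' @param config Pipeline configuration.
#' @return A `data.frame` with one row per (subject, session, method):
#'   estimated and true sbp/dbp/map, plus `valid`.
#' @export
run_cohort <- function(n_subjects = 20, n_sessions = 3, seed = 42,
                       snr_db = 20, duration = 25, session_bp_sd = 4,
                       methods = c("p_beta", "regression"),
                       regression_scope = c("pooled", "subject"),
                       ranges = cohort_ranges(),
                       config = default_config()) {
  methods <- match.arg(methods, c("p_beta", "regression"),
                       several.ok = TRUE)
  regression_scope <- match.arg(regression_scope)
  if ("regression" %in% methods && n_sessions < 3) {
    abort_config("the regression arm needs >= 3 sessions (2 anchors + 1 test)")
  }
  cohort <- make_cohort(n_subjects, seed = seed, ranges = ranges)
  dims <- reference_dims(cohort)
  sims <- lapply(cohort, function(p) {
    lapply(seq_len(n_sessions), function(s) {
      simulate_session(p, session = s, duration = duration,
                       sensor_distance = config$sensor_distance_m,
                       snr_db = snr_db, session_bp_sd = session_bp_sd)
    })
  })
  truth_bp <- function(sim) c(sbp = sim$truth$sbp, dbp = sim$truth$dbp,
                              map = sim$truth$map)
  cals <- lapply(seq_along(cohort), function(i) {
    calibrate(sims[[i]][[1]]$record, truth_bp(sims[[i]][[1]]), dims, config)
  })
  # cohort-level diameter model from the calibration sessions
  pn <- vapply(seq_along(cohort), function(i) {
    process_ppg(sims[[i]][[1]]$record, config)$ppg_norm
  }, numeric(1))
  dm <- tryCatch(fit_diameter_model(pn, dims$dd_mm * 1e-3),
                 pulsebp_calibration_error = function(e) NULL)
  cals <- lapply(cals, function(cl) { cl$diameter_model <- dm; cl })
  cals2 <- pooled <- NULL
  if ("regression" %in% methods) {
    cals2 <- lapply(seq_along(cohort), function(i) {
      calibrate(sims[[i]][[2]]$record, truth_bp(sims[[i]][[2]]), dims,
                config)
    })
    if (regression_scope == "pooled") {
      pooled <- fit_regression_pooled(c(cals, cals2))
    }
  }
  rows <- list()
  for (i in seq_along(cohort)) {
    if ("p_beta" %in% methods) {
      for (s in 2:n_sessions) {
        est <- estimate(sims[[i]][[s]]$record, cals[[i]], "p_beta", config)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = cohort[[i]]$subject_id, session = s,
          method = "p_beta", est_sbp = est$sbp, est_dbp = est$dbp,
          est_map = est$map, ref_sbp = sims[[i]][[s]]$truth$sbp,
          ref_dbp = sims[[i]][[s]]$truth$dbp,
          ref_map = sims[[i]][[s]]$truth$map, valid = est$valid,
          stringsAsFactors = FALSE)
      }
    }
    if ("regression" %in% methods) {
      calr <- if (regression_scope == "pooled") {
        cl <- cals[[i]]
        cl$regression <- pooled
        cl
      } else {
        fit_regression_arm(list(cals[[i]], cals2[[i]]))
      }
      for (s in 3:n_sessions) {
        est <- estimate(sims[[i]][[s]]$record, calr, "regression", config)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = cohort[[i]]$subject_id, session = s,
          method = "regression", est_sbp = est$sbp, est_dbp = est$dbp,
          est_map = est$map, ref_sbp = sims[[i]][[s]]$truth$sbp,
          ref_dbp = sims[[i]][[s]]$truth$dbp,
          ref_map = sims[[i]][[s]]$truth$map, valid = est$valid,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
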