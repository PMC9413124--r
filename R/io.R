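# File formats and configuration: the long-format CSV signal dialect with a
# JSON sidecar, the pipeline configuration, and (de)serialization of
# calibration states and estimates.

#' Default pipeline configuration
#'
#' Every default mirrors the device's printed operating point where one
#' exists: 0.7/9.5 Hz digital band-pass, blood density 1.06 g/mL, tracking
#' coefficient 0.76, specific-heat ratio 1.4, 8000 pF parasitic
#' capacitance, 10.6 Hz analog low-pass, 18x gain, 5 kHz piezo and 100 Hz
#' PPG sampling with an 18-bit PPG ADC. The inter-sensor distance (2 cm)
#' is a configurable device property, not a published one.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 42,
    sensor_distance_m = 0.02,
    rho_blood = 1060,
    k = 0.76,
    tracking_variant = "printed",
    afe = unclass(afe_params()),
    dsp = list(fs_work = 500, f_hp = 0.7, f_lp = 9.5, decay_s = 2,
               threshold_frac = 0.5, refractory_s = 0.3,
               pair_window_s = 0.15, template_refine = TRUE,
               refine_win_s = 0.1, refine_maxlag_s = 0.02),
    pir = list(eq12_reading = "quotient", alpha = NA),
    quality = list(min_paired_beats = 3, max_interval_cv = 0.25,
                   min_pir = 1.001),
    simulation = list(n_subjects = 20, n_sessions = 3, duration_s = 25,
                      fs_piezo = 5000, fs_ppg = 100, snr_db = 20,
                      session_bp_sd = 4, ranges = cohort_ranges())
  )
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort_config(sprintf("unknown configuration key(s): %s",
                         paste0(path, unknown, collapse = ", ")))
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load a pipeline configuration from JSON
#'
#' Unknown keys are rejected; omitted keys keep their defaults.
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @return Configuration list with attribute `"hash"` (fingerprint for
#'   logging).
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- merge_config(cfg, user)
  }
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

#' @rdname load_config
#' @param config Configuration list.
#' @export
config_hash <- function(config) {
  string_hash(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Write a session to the CSV signal dialect
#'
#' Long format, one row per sample, header `time_s,channel,value,unit`;
#' the two sampling rates (piezo vs PPG) cannot share a time axis, so the
#' per-channel rates live in a JSON sidecar (same basename, `.json`)
#' together with the subject, session label and sensor distance.
#'
#' @param record A [session_record()].
#' @param path Output CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_session <- function(record, path) {
  stopifnot(inherits(record, "session_record"))
  parts <- lapply(names(record$signals), function(role) {
    sig <- record$signals[[role]]
    data.table::data.table(time_s = signal_times(sig), channel = role,
                           value = sig$samples, unit = sig$unit)
  })
  data.table::fwrite(data.table::rbindlist(parts), path)
  meta <- list(
    subject_id = record$subject_id,
    session = record$label,
    sensor_distance_m = record$sensor_distance,
    duration_s = record$duration,
    fs = lapply(record$signals, `[[`, "fs"),
    units = lapply(record$signals, `[[`, "unit")
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a session from the CSV signal dialect
#'
#' Validates channel presence, per-channel time monotonicity and
#' consistency with the declared sampling rate.
#'
#' @param path CSV path written by [write_session()] (sidecar required).
#' @return A [session_record()].
#' @export
read_session <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    abort_format(sprintf("missing sidecar JSON: %s", sc))
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  tab <- data.table::fread(path)
  need <- c("time_s", "channel", "value", "unit")
  if (!all(need %in% names(tab))) {
    abort_format("CSV must have columns time_s,channel,value,unit")
  }
  signals <- list()
  for (role in c("piezo_proximal", "piezo_distal", "ppg")) {
    rows <- tab[tab$channel == role, ]
    if (!nrow(rows)) {
      abort_format(sprintf("file is missing the '%s' channel", role))
    }
    fs <- meta$fs[[role]]
    if (is.null(fs)) abort_format(sprintf("sidecar lacks fs for '%s'", role))
    tm <- rows$time_s
    if (any(diff(tm) <= 0)) {
      bad <- which(diff(tm) <= 0)[1] + 1L
      abort_format(sprintf("non-monotone time in '%s' at row %d", role, bad))
    }
    jitter <- max(abs(diff(tm) - 1 / fs))
    if (jitter > 1e-6) {
      abort_format(sprintf(
        "'%s' time axis inconsistent with declared fs = %g Hz (max jitter %g s)",
        role, fs, jitter))
    }
    signals[[role]] <- pulse_signal(rows$value, fs = fs,
                                    unit = rows$unit[1], role = role)
  }
  session_record(
    subject_id = meta$subject_id, signals = signals,
    duration = meta$duration_s %||%
      (length(signals$ppg$samples) / signals$ppg$fs),
    sensor_distance = meta$sensor_distance_m,
    label = meta$session %||% "s1"
  )
}

#' Serialize / restore a calibration state
#'
#' @param cal A [calibration_state()].
#' @param path JSON path.
#' @return `path` (write) or the restored [calibration_state()] (read).
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_state"))
  out <- unclass(cal)
  if (!is.null(out$regression)) {
    out$regression <- lapply(out$regression, unclass)
  }
  if (!is.null(out$diameter_model)) {
    out$diameter_model <- unclass(out$diameter_model)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cal <- calibration_state(
    subject_id = raw$subject_id, beta = raw$beta %||% NA_real_,
    alpha = raw$alpha %||% NA_real_, k = raw$k %||% 0.76,
    dd_ref = raw$dd_ref %||% NA_real_,
    delta_d_ref = raw$delta_d_ref %||% NA_real_,
    ref_bp = unlist(raw$ref_bp),
    anchors = if (!is.null(raw$anchors)) as.data.frame(raw$anchors) else NULL,
    calibrated_at = raw$calibrated_at %||% NA
  )
  if (!is.null(raw$regression)) {
    cal$regression <- lapply(raw$regression,
                             function(cc) regression_coeffs(cc$K1, cc$K2))
  }
  if (!is.null(raw$diameter_model) && !is.null(raw$diameter_model$slope)) {
    dm <- raw$diameter_model
    cal$diameter_model <- structure(
      list(slope = dm$slope, intercept = dm$intercept,
           alpha = dm$alpha %||% NA_real_, fit_r2 = dm$fit_r2 %||% NA_real_,
           range = unlist(dm$range)),
      class = "diameter_model")
  }
  cal
}
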