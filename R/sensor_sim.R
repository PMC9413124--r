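# Synthetic-data generator: ground-truth subjects, two-site pulse waveforms
# with a controlled transit delay, piezo chamber pressure physics, and
# Beer-Lambert PPG optics.

ADC_PPG_BITS <- 18L
ADC_PPG_MAX <- 2^18 - 1

#' PPG optics parameters (Beer-Lambert)
#'
#' The received intensity is `I = I0 * exp(-alpha_dc * d_dc) *
#' exp(-alpha * D)` for arterial diameter `D`: a bulk (DC) attenuation from
#' the static tissue path and an arterial attenuation proportional to the
#' instantaneous diameter. Beat maxima/minima are
#' `IH = I0 * exp(-alpha_dc * d_dc) * exp(-alpha * Dd)` and
#' `IL = ... * exp(-alpha * Ds)`, so `IH / IL = exp(alpha * deltaD)`.
#'
#' @param I0 Source intensity (ADC counts before attenuation).
#' @param alpha_dc Bulk absorbance coefficient (1/m), the product of the
#'   tissue absorbance coefficient and chromophore concentration.
#' @param d_dc Static (DC) photon path length in tissue (m).
#' @param alpha Arterial absorbance coefficient (1/m).
#' @return An object of class `optics_params`.
#' @export
optics_params <- function(I0 = 2e7, alpha_dc = 500, d_dc = 0.01,
                          alpha = 500) {
  for (nm in c("I0", "alpha_dc", "d_dc", "alpha")) {
    check_scalar(get(nm), nm)
  }
  dc <- I0 * exp(-alpha_dc * d_dc)
  if (dc > ADC_PPG_MAX) {
    abort_config("DC intensity exceeds the 18-bit ADC range")
  }
  structure(list(I0 = I0, alpha_dc = alpha_dc, d_dc = d_dc, alpha = alpha),
            class = "optics_params")
}

#' Piezo sensor chamber parameters
#'
#' @param V Chamber volume (m^3).
#' @param A Membrane cross-sectional area (m^2).
#' @param gamma Ratio of specific heats; approximately 1.4 for air.
#' @param PA Internal chamber pressure (Pa).
#' @param rho_air Air density (kg/m^3).
#' @return An object of class `chamber_params`.
#' @export
chamber_params <- function(V = 4e-7, A = 7.85e-5, gamma = 1.4,
                           PA = 101325, rho_air = 1.204) {
  for (nm in c("V", "A", "gamma", "PA", "rho_air")) check_scalar(get(nm), nm)
  structure(list(V = V, A = A, gamma = gamma, PA = PA, rho_air = rho_air),
            class = "chamber_params")
}

#' Chamber pressure response to membrane displacement
#'
#' Adiabatic compression of the sealed sensor chamber: a membrane travel
#' `x` changes the chamber volume by `A * x`, producing a pressure
#' `Pa = -gamma * PA * A * x / V` (inward displacement raises the pressure
#' magnitude). Linear and memoryless; valid while `|A * x| << V`.
#'
#' @param displacement A [pulse_signal()] of membrane travel (m).
#' @param params A [chamber_params()].
#' @return A [pulse_signal()] of chamber pressure (Pa).
#' @export
chamber_response <- function(displacement, params = chamber_params()) {
  stopifnot(inherits(displacement, "pulse_signal"),
            inherits(params, "chamber_params"))
  if (max(abs(displacement$samples)) * params$A >= params$V) {
    abort_simulation("membrane displacement violates the chamber volume bound")
  }
  signal_with(displacement,
              -params$gamma * params$PA * params$A * displacement$samples /
                params$V,
              unit = "Pa")
}

# ---- beat template -------------------------------------------------------

default_beat_shape <- function() {
  list(systolic_center = 0.18, systolic_width = 0.05,
       dicrotic_center = 0.55, dicrotic_width = 0.09, dicrotic_amp = 0.35)
}

# Single-beat template on cycle phase (Gaussian systolic peak plus a
# dicrotic reflection); support effectively within phase (-0.5, 1.5).
beat_shape_eval <- function(phase, shape = default_beat_shape()) {
  exp(-0.5 * ((phase - shape$systolic_center) / shape$systolic_width)^2) +
    shape$dicrotic_amp *
      exp(-0.5 * ((phase - shape$dicrotic_center) / shape$dicrotic_width)^2)
}

# Min/max of the periodized template over one cycle (for normalizing the
# PPG diameter drive to [0, 1]).
beat_shape_range <- function(shape = default_beat_shape()) {
  ph <- seq(0, 1, by = 1e-4)
  g <- beat_shape_eval(ph, shape) + beat_shape_eval(ph - 1, shape) +
    beat_shape_eval(ph + 1, shape)
  range(g)
}

# Analytic phase of the template's maximum upslope (the foot fiducial the
# detector reports); the dicrotic lobe is negligible there.
beat_shape_fiducial_phase <- function(shape = default_beat_shape()) {
  shape$systolic_center - shape$systolic_width
}

# Beat onset times with +/- `jitter` fractional cycle jitter.
beat_onsets <- function(heart_rate, duration, seed, jitter = 0.02,
                        t0 = 0.4) {
  period <- 60 / heart_rate
  with_seed(seed, {
    onsets <- t0
    repeat {
      nxt <- onsets[length(onsets)] +
        period * (1 + stats::runif(1, -jitter, jitter))
      if (nxt >= duration) break
      onsets <- c(onsets, nxt)
    }
    onsets
  })
}

# Evaluate a pulse train at (sorted) times t: sum of per-beat templates.
pulse_train_eval <- function(t, onsets, periods, shape = default_beat_shape()) {
  s <- numeric(length(t))
  for (i in seq_along(onsets)) {
    lo <- onsets[i] - 0.5 * periods[i]
    hi <- onsets[i] + 1.5 * periods[i]
    i1 <- findInterval(lo, t) + 1L
    i2 <- findInterval(hi, t)
    if (i2 >= i1) {
      sel <- i1:i2
      ph <- (t[sel] - onsets[i]) / periods[i]
      s[sel] <- s[sel] + beat_shape_eval(ph, shape)
    }
  }
  s
}

# ---- cohort --------------------------------------------------------------

#' Default physiological parameter ranges for a simulated cohort
#'
#' Uniform sampling ranges: mean arterial pressure 70-120 mmHg, heart rate
#' 50-100 bpm, end-diastolic diameter 2.0-3.0 mm, fractional diameter
#' excursion 3-9%, wall thickness 0.2-0.4 mm. Stiffness coefficients span
#' a zero-pressure modulus of 50-90 kPa with an exponential pressure
#' coefficient of 0.014-0.018 per mmHg, which place the radial wave speed
#' in the physiological few-m/s range over the pressure span. The tracking
#' coefficient `k` is fixed at 0.76 for the whole cohort.
#'
#' @return Named list of `c(lo, hi)` ranges.
#' @export
cohort_ranges <- function() {
  list(
    map_mmhg = c(70, 120),
    heart_rate = c(50, 100),
    dd_mm = c(2.0, 3.0),
    delta_ratio = c(0.03, 0.09),
    h_mm = c(0.2, 0.4),
    e0_kpa = c(50, 90),
    xi_per_mmhg = c(0.014, 0.018),
    k = c(0.76, 0.76),
    depth_mm = c(2.0, 3.0)
  )
}

#' Ground-truth simulated subject
#'
#' Builds an internally consistent subject: the diastolic and systolic
#' pressures follow the tracking decomposition (`DBP = k * MAP`,
#' `SBP = MAP + (1 - k) * DBP`) so the inverse model is recoverable, and
#' the subject's wave speed at any pressure follows the Moens-Korteweg
#' relation with the exponential pressure-dependent modulus.
#'
#' @param subject_id Label.
#' @param true_map Mean arterial pressure (mmHg).
#' @param heart_rate Beats per minute.
#' @param arterial An [arterial_state()].
#' @param stiffness A [stiffness_params()].
#' @param optics An [optics_params()].
#' @param depth_mm Radial artery depth (mm); carried for realism, unused by
#'   the models.
#' @param seed Per-subject RNG seed.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, true_map, heart_rate, arterial,
                            stiffness, optics = optics_params(),
                            depth_mm = 2.5, seed = 1L) {
  check_scalar(true_map, "true_map")
  check_scalar(heart_rate, "heart_rate")
  stopifnot(inherits(arterial, "arterial_state"),
            inherits(stiffness, "stiffness_params"),
            inherits(optics, "optics_params"))
  k <- stiffness$k
  dbp <- true_map * k
  sbp <- true_map + (1 - k) * dbp
  pwv <- mk_pwv(arterial, youngs_modulus(stiffness, true_map))
  beta <- beta_calibrate(arterial, pwv, true_map)
  structure(
    list(subject_id = subject_id, true_sbp = sbp, true_dbp = dbp,
         true_map = true_map, heart_rate = heart_rate, arterial = arterial,
         stiffness = stiffness, optics = optics, depth_mm = depth_mm,
         true_pwv = pwv, true_beta = beta, seed = as.integer(seed)),
    class = "subject_profile"
  )
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "<subject_profile %s: SBP/DBP/MAP %.1f/%.1f/%.1f mmHg, HR %.0f, PWV %.2f m/s>\n",
    x$subject_id, x$true_sbp, x$true_dbp, x$true_map, x$heart_rate,
    x$true_pwv))
  invisible(x)
}

#' Generate a simulated cohort
#'
#' Draws `n_subjects` ground-truth subjects with parameters uniform over
#' `ranges`. Deterministic given `seed`.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed RNG seed.
#' @param ranges Parameter ranges as from [cohort_ranges()].
#' @param optics Shared [optics_params()] (the optics describe the sensor,
#'   not the subject).
#' @return List of [subject_profile()] objects.
#' @export
make_cohort <- function(n_subjects, seed = 42L, ranges = cohort_ranges(),
                        optics = optics_params()) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    abort_config("'n_subjects' must be >= 1")
  }
  defaults <- cohort_ranges()
  unknown <- setdiff(names(ranges), names(defaults))
  if (length(unknown)) {
    abort_config(paste("unknown range name(s):", paste(unknown, collapse = ", ")))
  }
  ranges <- utils::modifyList(defaults, ranges)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (!is.numeric(r) || length(r) != 2L || anyNA(r) || r[1] > r[2] ||
        r[1] <= 0) {
      abort_config(sprintf("invalid range for '%s'", nm))
    }
  }
  n_subjects <- as.integer(n_subjects)
  with_seed(seed, {
    draw <- function(nm) stats::runif(n_subjects, ranges[[nm]][1], ranges[[nm]][2])
    map <- draw("map_mmhg")
    hr <- draw("heart_rate")
    dd <- draw("dd_mm") * 1e-3
    dratio <- draw("delta_ratio")
    h <- draw("h_mm") * 1e-3
    e0 <- draw("e0_kpa") * 1e3
    xi <- draw("xi_per_mmhg")
    k <- draw("k")
    depth <- draw("depth_mm")
    seeds <- sample.int(1e8, n_subjects)
    lapply(seq_len(n_subjects), function(i) {
      subject_profile(
        subject_id = sprintf("S%03d", i),
        true_map = map[i], heart_rate = hr[i],
        arterial = arterial_state(Dd = dd[i], deltaD = dratio[i] * dd[i],
                                  h = h[i]),
        stiffness = stiffness_params(E0 = e0[i], xi = xi[i], k = k[i]),
        optics = optics, depth_mm = depth[i], seed = seeds[i]
      )
    })
  })
}

#' Ultrasound-surrogate reference dimension table
#'
#' The cohort's ground-truth arterial dimensions in the external reference
#' schema (`subject_id, dd_mm, delta_d_mm, depth_mm`). This synthetic table
#' stands in for ultrasound-derived measurements.
#'
#' @param cohort List of [subject_profile()].
#' @return A `data.frame`.
#' @export
reference_dims <- function(cohort) {
  data.frame(
    subject_id = vapply(cohort, `[[`, "", "subject_id"),
    dd_mm = vapply(cohort, function(p) p$arterial$Dd * 1e3, numeric(1)),
    delta_d_mm = vapply(cohort, function(p) p$arterial$deltaD * 1e3, numeric(1)),
    depth_mm = vapply(cohort, `[[`, 0, "depth_mm"),
    stringsAsFactors = FALSE
  )
}

# ---- signal generation ---------------------------------------------------

#' Generate a two-site pulse waveform pair with known transit delay
#'
#' Channel 2 is channel 1 delayed by `true_ptt = sensor_distance / PWV`,
#' where the wave speed follows the subject's Moens-Korteweg model at
#' `map`. The delay is exact: both channels are evaluated analytically
#' from the same beat-template train, so no interpolation error enters.
#'
#' @param profile A [subject_profile()].
#' @param duration Record length (s), >= 5.
#' @param fs Sampling rate (Hz), >= 500.
#' @param sensor_distance Inter-sensor distance (m).
#' @param map Pressure at which to evaluate the wave speed (mmHg);
#'   defaults to the subject's baseline.
#' @param amplitude Peak membrane displacement (m).
#' @param onsets Optional beat onset times (s); defaults to a jittered
#'   train at the subject's heart rate, derived from the subject seed.
#' @param shape Beat template parameters.
#' @return List with `proximal` and `distal` [pulse_signal()] of membrane
#'   displacement, `true_ptt` (s), `true_pwv` (m/s), `onsets`, and
#'   `fiducial_times` (the analytic foot-fiducial times of channel 1).
#' @export
gen_pulse_pair <- function(profile, duration = 25, fs = 5000,
                           sensor_distance = 0.02,
                           map = profile$true_map, amplitude = 5e-5,
                           onsets = NULL, shape = default_beat_shape()) {
  stopifnot(inherits(profile, "subject_profile"))
  if (duration < 5) abort_invalid("'duration' must be >= 5 s")
  if (fs < 500) abort_invalid("'fs' must be >= 500 Hz")
  pwv <- mk_pwv(profile$arterial, youngs_modulus(profile$stiffness, map))
  ptt <- sensor_distance / pwv
  if (sensor_distance > 0 && ptt < 2 / fs) {
    abort_config(sprintf("transit delay %.3g s unresolvable at fs = %g Hz",
                         ptt, fs))
  }
  if (is.null(onsets)) {
    onsets <- beat_onsets(profile$heart_rate, duration, profile$seed)
  }
  periods <- c(diff(onsets), 60 / profile$heart_rate)
  t <- (0:(round(duration * fs) - 1)) / fs
  x1 <- amplitude * pulse_train_eval(t, onsets, periods, shape)
  x2 <- amplitude * pulse_train_eval(t - ptt, onsets, periods, shape)
  list(
    proximal = pulse_signal(x1, fs, unit = "m", role = "piezo_proximal"),
    distal = pulse_signal(x2, fs, unit = "m", role = "piezo_distal"),
    true_ptt = ptt, true_pwv = pwv, onsets = onsets,
    fiducial_times = onsets + beat_shape_fiducial_phase(shape) * periods
  )
}

#' Generate a Beer-Lambert PPG signal
#'
#' The arterial diameter follows the (normalized) beat template between
#' `Dd` and `Ds`; the received intensity follows the Beer-Lambert optics of
#' [optics_params()], so over each cycle the clean intensity swings between
#' `IH` (diastole) and `IL` (systole) with `IH / IL = exp(alpha * deltaD)`.
#'
#' @param profile A [subject_profile()].
#' @param duration Record length (s).
#' @param fs Sampling rate (Hz), >= 50 (the device samples at 100 Hz).
#' @param onsets Optional beat onsets shared with the piezo channels (same
#'   cardiac cycle; the optical site sits between the piezo pair, so no
#'   extra transit delay is applied by default).
#' @param quantize Quantize to the 18-bit ADC grid (default TRUE; the
#'   session simulator quantizes after adding noise instead).
#' @param shape Beat template parameters.
#' @return A [pulse_signal()] in ADC counts (role `"ppg"`).
#' @export
gen_ppg <- function(profile, duration = 25, fs = 100, onsets = NULL,
                    quantize = TRUE, shape = default_beat_shape()) {
  stopifnot(inherits(profile, "subject_profile"))
  if (fs < 50) abort_invalid("'fs' must be >= 50 Hz")
  op <- profile$optics
  art <- profile$arterial
  if (is.null(onsets)) {
    onsets <- beat_onsets(profile$heart_rate, duration, profile$seed)
  }
  periods <- c(diff(onsets), 60 / profile$heart_rate)
  t <- (0:(round(duration * fs) - 1)) / fs
  g <- pulse_train_eval(t, onsets, periods, shape)
  rng <- beat_shape_range(shape)
  g01 <- (g - rng[1]) / (rng[2] - rng[1])
  D <- art$Dd + art$deltaD * pmin(pmax(g01, 0), 1)
  intensity <- op$I0 * exp(-op$alpha_dc * op$d_dc) * exp(-op$alpha * D)
  if (any(intensity <= 0)) abort_config("optics produced non-positive intensity")
  if (quantize) intensity <- quantize_ppg_samples(intensity)
  pulse_signal(intensity, fs, unit = "counts", role = "ppg")
}

quantize_ppg_samples <- function(x) pmin(pmax(round(x), 0), ADC_PPG_MAX)

#' Quantize a PPG signal to the 18-bit ADC grid
#'
#' @param signal A [pulse_signal()].
#' @return The quantized [pulse_signal()].
#' @export
quantize_ppg <- function(signal) {
  stopifnot(inherits(signal, "pulse_signal"))
  signal_with(signal, quantize_ppg_samples(signal$samples))
}

#' Ground-truth PPG intensity levels for a subject
#'
#' @param profile A [subject_profile()].
#' @return List with the clean `ih`, `il` and `pir = exp(alpha * deltaD)`.
#' @export
ppg_truth <- function(profile) {
  op <- profile$optics
  art <- profile$arterial
  dc <- op$I0 * exp(-op$alpha_dc * op$d_dc)
  list(ih = dc * exp(-op$alpha * art$Dd),
       il = dc * exp(-op$alpha * art$Ds),
       pir = exp(op$alpha * art$deltaD))
}

#' Add white Gaussian noise at a target SNR
#'
#' Noise is scaled so `10 * log10(P_signal / P_noise) = snr_db`, with the
#' signal power taken as the variance of the clean samples (the AC power;
#' a DC-dominated signal such as raw PPG would otherwise make the SNR
#' meaningless). `snr_db = Inf` returns the signal unchanged.
#' Deterministic given `seed`.
#'
#' @param signal A [pulse_signal()].
#' @param snr_db Target signal-to-noise ratio (dB).
#' @param seed RNG seed.
#' @param reference `"ac"` (variance, default) or `"rms"` (mean square).
#' @return The noisy [pulse_signal()].
#' @export
add_noise <- function(signal, snr_db, seed = 1L,
                      reference = c("ac", "rms")) {
  stopifnot(inherits(signal, "pulse_signal"))
  reference <- match.arg(reference)
  if (!is.numeric(snr_db) || is.na(snr_db)) abort_invalid("'snr_db' must be numeric")
  if (is.infinite(snr_db) && snr_db > 0) return(signal)
  p <- if (reference == "ac") stats::var(signal$samples) else
    mean(signal$samples^2)
  sigma <- sqrt(p) * 10^(-snr_db / 20)
  noisy <- with_seed(seed, signal$samples +
                       stats::rnorm(length(signal$samples), 0, sigma))
  signal_with(signal, noisy)
}

# ---- full session --------------------------------------------------------

#' Simulate one measurement session for a subject
#'
#' Generates the complete sensed record the device would produce over one
#' session: a session-specific blood pressure (baseline plus a zero-mean
#' normal visit-to-visit offset), two piezo channels carried through the
#' chamber physics, piezo transduction and the analog front end, plus the
#' Beer-Lambert PPG channel, all with additive noise at `snr_db`
#' (PPG quantized to 18 bits after the noise).
#'
#' @param profile A [subject_profile()].
#' @param session Session index (1-based); session seeds derive from the
#'   subject seed and this index, so records are reproducible.
#' @param duration Record length (s).
#' @param fs_piezo,fs_ppg Channel sampling rates (Hz).
#' @param sensor_distance Inter-sensor distance (m).
#' @param snr_db Additive-noise SNR (dB); `Inf` for noiseless.
#' @param session_bp_sd Standard deviation of the visit-to-visit MAP offset
#'   (mmHg); 0 pins every session at the subject baseline.
#' @param apply_afe Carry the piezo channels through the analog front end.
#' @param afe An [afe_params()].
#' @param chamber A [chamber_params()].
#' @param piezo_sensitivity Piezo transduction constant (V/Pa).
#' @param displacement_amp Peak membrane displacement (m).
#' @return List with `record` (a [session_record()]) and `truth` (the
#'   session's true `sbp`, `dbp`, `map`, `ptt`, `pwv` and beat `onsets`).
#' @export
simulate_session <- function(profile, session = 1L, duration = 25,
                             fs_piezo = 5000, fs_ppg = 100,
                             sensor_distance = 0.02, snr_db = 20,
                             session_bp_sd = 4, apply_afe = TRUE,
                             afe = afe_params(), chamber = chamber_params(),
                             piezo_sensitivity = 2e-5,
                             displacement_amp = 5e-5) {
  stopifnot(inherits(profile, "subject_profile"))
  base_seed <- profile$seed + 97L * as.integer(session)
  delta <- if (session_bp_sd > 0) {
    with_seed(base_seed, stats::rnorm(1, 0, session_bp_sd))
  } else 0
  map_s <- profile$true_map + delta
  k <- profile$stiffness$k
  dbp_s <- map_s * k
  sbp_s <- map_s + (1 - k) * dbp_s
  onsets <- beat_onsets(profile$heart_rate, duration, base_seed + 1L)
  pair <- gen_pulse_pair(profile, duration, fs_piezo, sensor_distance,
                         map = map_s, amplitude = displacement_amp,
                         onsets = onsets)
  to_voltage <- function(sig, seed) {
    v <- chamber_response(sig, chamber)
    v <- signal_with(v, piezo_sensitivity * v$samples, unit = "V")
    if (apply_afe) v <- afe_apply(v, afe)
    add_noise(v, snr_db, seed)
  }
  prox <- to_voltage(pair$proximal, base_seed + 2L)
  dist <- to_voltage(pair$distal, base_seed + 3L)
  ppg <- gen_ppg(profile, duration, fs_ppg, onsets = onsets,
                 quantize = FALSE)
  ppg <- quantize_ppg(add_noise(ppg, snr_db, base_seed + 4L))
  record <- session_record(
    subject_id = profile$subject_id,
    signals = list(piezo_proximal = prox, piezo_distal = dist, ppg = ppg),
    duration = duration, sensor_distance = sensor_distance,
    label = sprintf("s%d", as.integer(session))
  )
  list(record = record,
       truth = list(sbp = sbp_s, dbp = dbp_s, map = map_s,
                    ptt = pair$true_ptt, pwv = pair$true_pwv,
                    onsets = onsets, fiducial_times = pair$fiducial_times))
}
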