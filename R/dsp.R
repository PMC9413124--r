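# Beat detection and PTT extraction: dynamic-threshold fiducial detection on
# band-pass filtered pulse waves, inter-channel pairing, median aggregation.

#' Per-beat fiducial features
#'
#' @param foot_times Foot fiducial time per beat (s): the sub-sample refined
#'   time of the maximum systolic upslope, used for transit timing.
#' @param peak_times Systolic peak time per beat (s).
#' @param amplitudes Foot-to-peak amplitude per beat (signal units).
#' @param valid Per-beat quality flag.
#' @param fs Sampling rate the beats were detected at (Hz).
#' @return An object of class `beat_features`.
#' @export
beat_features <- function(foot_times = numeric(), peak_times = numeric(),
                          amplitudes = numeric(), valid = logical(),
                          fs = NA_real_) {
  if (length(foot_times) > 1L && any(diff(foot_times) <= 0)) {
    abort_invalid("'foot_times' must be strictly increasing")
  }
  if (any(foot_times > peak_times)) {
    abort_invalid("each foot must precede its peak")
  }
  structure(
    list(foot_times = foot_times, peak_times = peak_times,
         amplitudes = amplitudes, valid = valid, fs = fs,
         n_beats = length(foot_times)),
    class = "beat_features"
  )
}

#' @export
print.beat_features <- function(x, ...) {
  cat(sprintf("<beat_features: %d beats (%d valid) @ %g Hz>\n", x$n_beats,
              sum(x$valid), x$fs))
  invisible(x)
}

# Three-point parabolic vertex offset (in samples) around index i of y.
parabolic_offset <- function(y, i) {
  den <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (!is.finite(den) || den == 0) return(0)
  d <- 0.5 * (y[i - 1] - y[i + 1]) / den
  if (abs(d) > 1) 0 else d
}

#' Detect beats with a dynamic threshold
#'
#' Runs an exponentially decaying running-peak tracker (time constant
#' `decay_s`); a beat is declared at each upward crossing of
#' `threshold_frac` times the running peak, subject to a refractory period.
#' For each beat the systolic peak, the maximum-upslope point (sub-sample
#' refined by a parabolic fit on the first difference; this is the reported
#' foot fiducial used for transit timing) and the preceding local minimum
#' are located. Beats whose inter-beat interval falls outside
#' [0.3, 2.0] s are flagged invalid.
#'
#' The input is expected to be band-pass filtered ([bpf_apply()]); a signal
#' with no detectable beats yields an empty result, not an error.
#'
#' @param signal A [pulse_signal()], band-pass filtered, >= 3 s long.
#' @param decay_s Running-peak decay time constant (s).
#' @param threshold_frac Fraction of the running peak used as threshold.
#' @param refractory_s Refractory period after each detection (s); also the
#'   minimum accepted separation between consecutive feet.
#' @param amp_frac Beats with foot-to-peak amplitude below `amp_frac` times
#'   the upper-quartile amplitude are flagged invalid; this rejects
#'   dicrotic-wave detections, which at low heart rates can outlast the
#'   refractory period.
#' @return A [beat_features()].
#' @export
detect_beats <- function(signal, decay_s = 2, threshold_frac = 0.5,
                         refractory_s = 0.3, amp_frac = 0.4) {
  stopifnot(inherits(signal, "pulse_signal"))
  if (signal_duration(signal) < 3) abort_invalid("need >= 3 s of signal")
  x <- signal$samples
  fs <- signal$fs
  n <- length(x)
  dt <- 1 / fs
  decay <- exp(-dt / decay_s)
  refr <- round(refractory_s * fs)
  rp <- max(x[seq_len(min(n, round(2 * fs)))])
  feet <- numeric(0)
  peaks <- numeric(0)
  amps <- numeric(0)
  if (rp > 0) {
    i <- 2L
    while (i <= n) {
      rp <- max(rp * decay, x[i])
      if (x[i] >= threshold_frac * rp && x[i - 1] < threshold_frac * rp) {
        j2 <- min(n, i + round(0.5 * fs))
        ip <- i - 1L + which.max(x[i:j2])
        j1 <- max(2L, ip - round(0.4 * fs))
        if (ip + 1L <= n && ip > j1) {
          d <- (x[(j1 + 1):(ip + 1)] - x[(j1 - 1):(ip - 1)]) / 2
          iu <- j1 - 1L + which.max(d)
          if (iu > 2L && iu < n - 1L && iu < ip) {
            dloc <- (x[(iu):(iu + 2)] - x[(iu - 2):(iu)]) / 2
            delta <- parabolic_offset(dloc, 2L)
            tfoot <- min((iu - 1 + delta) * dt, (ip - 1) * dt)
            if (!length(feet) || tfoot > feet[length(feet)] + refractory_s) {
              feet <- c(feet, tfoot)
              peaks <- c(peaks, (ip - 1) * dt)
              # amplitude from the local minimum preceding the upslope
              k <- iu
              while (k > 2L && x[k - 1] < x[k]) k <- k - 1L
              amps <- c(amps, x[ip] - x[k])
            }
          }
        }
        # advance past the refractory window, keeping the peak tracker fed
        iend <- min(n, i + refr)
        rp <- max(rp * decay^(iend - i), max(x[i:iend]))
        i <- iend
      }
      i <- i + 1L
    }
  }
  nb <- length(feet)
  valid <- rep(TRUE, nb)
  if (nb == 0L) valid <- logical(0)
  if (nb >= 2L) {
    # amplitude gate first (dicrotic/edge rejections), then rhythm check
    # among the amplitude-valid feet
    valid <- amps >= amp_frac * stats::quantile(amps, 0.75, names = FALSE)
    vi <- which(valid)
    if (length(vi) >= 2L) {
      ibi <- diff(feet[vi])
      bad <- ibi < 0.3 | ibi > 2.0
      valid[vi[which(bad)]] <- FALSE
      valid[vi[which(bad) + 1L]] <- FALSE
    }
  }
  beat_features(feet, peaks, amps, valid, fs = fs)
}

# Flag beats too close to the record edges (band-pass transient region)
# as invalid.
trim_beat_edges <- function(beats, duration, trim = 1) {
  edge <- beats$foot_times < trim | beats$foot_times > duration - trim
  beats$valid <- beats$valid & !edge
  beats
}

#' Refine paired foot fiducials by template correlation
#'
#' Builds an ensemble-average beat template from the proximal channel's
#' valid beats and re-times every beat on both channels by the parabolic
#' peak of its correlation with that common template. Because one template
#' serves both channels, any constant centering offset cancels in the
#' transit-time difference; per-beat timing noise drops substantially
#' versus single-point fiducials because the whole systolic upslope
#' contributes. Refined times carry a common offset relative to the raw
#' foot times (the template's internal anchor), which is irrelevant for
#' transit timing.
#'
#' @param proximal_sig,distal_sig Band-pass filtered [pulse_signal()]s.
#' @param proximal,distal [beat_features()] detected on those signals.
#' @param win_s Half-width of the correlation window around each foot (s).
#' @param max_lag_s Maximum re-timing shift (s).
#' @return List with updated `proximal` and `distal` [beat_features()]
#'   (beats that cannot be refined near the record edges are flagged
#'   invalid).
#' @export
refine_feet_template <- function(proximal_sig, distal_sig, proximal,
                                 distal, win_s = 0.1, max_lag_s = 0.02) {
  stopifnot(inherits(proximal_sig, "pulse_signal"),
            inherits(distal_sig, "pulse_signal"))
  fs <- proximal_sig$fs
  w <- round(win_s * fs)
  maxlag <- max(2L, round(max_lag_s * fs))
  x1 <- proximal_sig$samples
  anchors <- function(b) round(b$foot_times * fs) + 1L
  ok_window <- function(i, n) i - w - maxlag >= 1 & i + w + maxlag <= n
  a1 <- anchors(proximal)
  usable <- proximal$valid & ok_window(a1, length(x1))
  if (sum(usable) < 3L) return(list(proximal = proximal, distal = distal))
  segs <- lapply(a1[usable], function(i) x1[(i - w):(i + w)])
  tmpl <- Reduce(`+`, segs) / length(segs)
  refine_channel <- function(sig, beats) {
    x <- sig$samples
    n <- length(x)
    a <- anchors(beats)
    ft <- beats$foot_times
    valid <- beats$valid
    lags <- -maxlag:maxlag
    for (b in seq_along(a)) {
      if (!valid[b]) next
      if (!ok_window(a[b], n)) { valid[b] <- FALSE; next }
      cc <- vapply(lags, function(l) {
        sum(x[(a[b] - w + l):(a[b] + w + l)] * tmpl)
      }, numeric(1))
      k <- which.max(cc)
      if (k == 1L || k == length(cc)) { valid[b] <- FALSE; next }
      off <- parabolic_offset(cc, k)
      ft[b] <- (a[b] - 1 + lags[k] + off) / fs
    }
    if (any(diff(ft) <= 0)) {
      # refinement must not reorder beats; drop any that collide
      bad <- c(FALSE, diff(ft) <= 0)
      ft <- ft[!bad]
      beats$peak_times <- beats$peak_times[!bad]
      beats$amplitudes <- beats$amplitudes[!bad]
      valid <- valid[!bad]
    }
    beat_features(ft, pmax(beats$peak_times, ft), beats$amplitudes, valid,
                  fs = fs)
  }
  list(proximal = refine_channel(proximal_sig, proximal),
       distal = refine_channel(distal_sig, distal))
}

#' Per-session PTT measurement
#'
#' @param per_beat_ptt Per-beat transit times (s) over paired beats.
#' @param sensor_distance Inter-sensor distance (m).
#' @return An object of class `ptt_measurement` with the per-beat values,
#'   their median, the wave speed `sensor_distance / median` and the number
#'   of beats used.
#' @export
ptt_measurement <- function(per_beat_ptt, sensor_distance) {
  if (!length(per_beat_ptt) || any(per_beat_ptt <= 0)) {
    abort_invalid("per-beat PTT values must be positive")
  }
  med <- stats::median(per_beat_ptt)
  structure(
    list(per_beat_ptt = per_beat_ptt, ptt_median = med,
         pwv = pwv_from_ptt(sensor_distance, med),
         n_beats_used = length(per_beat_ptt),
         sensor_distance = sensor_distance),
    class = "ptt_measurement"
  )
}

#' @export
print.ptt_measurement <- function(x, ...) {
  cat(sprintf("<ptt_measurement: median %.3f ms over %d beats, PWV %.2f m/s>\n",
              x$ptt_median * 1e3, x$n_beats_used, x$pwv))
  invisible(x)
}

#' Pair proximal/distal beats and measure PTT
#'
#' Each valid proximal foot is paired with the nearest later valid distal
#' foot within `max_lag_s`; the per-beat PTT is the foot-time difference,
#' the session PTT is the median over paired beats (robust to occasional
#' spurious or missed beats), and the wave speed is
#' `sensor_distance / median`.
#'
#' @param proximal,distal [beat_features()] for the two piezo channels.
#' @param sensor_distance Inter-sensor distance (m).
#' @param max_lag_s Pairing window (s); 150 ms covers physiological radial
#'   transit over a few centimetres with wide margin.
#' @return A [ptt_measurement()].
#' @export
pair_and_ptt <- function(proximal, distal, sensor_distance,
                         max_lag_s = 0.15) {
  stopifnot(inherits(proximal, "beat_features"),
            inherits(distal, "beat_features"))
  pf <- proximal$foot_times[proximal$valid]
  df <- distal$foot_times[distal$valid]
  if (length(pf) < 3L || length(df) < 3L) {
    abort_data("need >= 3 valid beats per channel to measure PTT")
  }
  ptts <- vapply(pf, function(tp) {
    lag <- df - tp
    lag <- lag[lag > 0 & lag <= max_lag_s]
    if (length(lag)) min(lag) else NA_real_
  }, numeric(1))
  ptts <- ptts[!is.na(ptts)]
  if (length(ptts) < 3L) abort_data("fewer than 3 paired beats")
  ptt_measurement(ptts, sensor_distance)
}
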