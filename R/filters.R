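# FIR design (windowed sinc, Hamming) and zero-phase application, plus the
# bilinear transform used to discretize the analog front-end stages.

# Ideal low-pass impulse response of odd length n, Hamming-windowed.
fir_lowpass <- function(n_taps, fc, fs) {
  if (n_taps %% 2 == 0) abort_config("FIR tap count must be odd")
  if (fc <= 0 || fc >= fs / 2) abort_config("cutoff must lie in (0, fs/2)")
  m <- (n_taps - 1) / 2
  k <- -m:m
  h <- ifelse(k == 0, 2 * fc / fs, sin(2 * pi * fc * k / fs) / (pi * k))
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n_taps - 1)) / (n_taps - 1))
  h <- h * w
  h / sum(h) # unity DC gain
}

fir_bandpass_proto <- function(n_taps, f1, f2, fs) {
  if (n_taps %% 2 == 0) abort_config("FIR tap count must be odd")
  m <- (n_taps - 1) / 2
  k <- -m:m
  lp <- function(fc) ifelse(k == 0, 2 * fc / fs, sin(2 * pi * fc * k / fs) / (pi * k))
  h <- lp(f2) - lp(f1)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n_taps - 1)) / (n_taps - 1))
  h * w
}

#' FIR frequency response magnitude
#'
#' @param h FIR coefficients.
#' @param f Frequencies (Hz) at which to evaluate.
#' @param fs Sampling rate (Hz).
#' @return `|H(f)|` at each frequency.
#' @export
fir_response <- function(h, f, fs) {
  k <- seq_along(h) - 1
  vapply(f, function(fi) {
    Mod(sum(h * exp(-2i * pi * fi * k / fs)))
  }, numeric(1))
}

# Zero-phase application of a symmetric odd-length FIR: FFT convolution with
# exact group-delay compensation of (n-1)/2 samples. The input is padded by
# odd reflection at both ends, which suppresses the start/end transients a
# long low-frequency filter would otherwise smear into the record.
fir_apply <- function(x, h) {
  n <- length(x)
  nh <- length(h)
  m <- (nh - 1) / 2
  p <- min(m, n - 1L)
  left <- 2 * x[1] - x[(p + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - p)]
  xp <- c(left, x, right)
  np <- length(xp)
  L <- 2^ceiling(log2(np + nh))
  X <- stats::fft(c(xp, rep(0, L - np)))
  H <- stats::fft(c(h, rep(0, L - nh)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / L
  y[(p + m + 1):(p + m + n)]
}

# Filter-design cache: band-pass tuning involves a small root search, so
# designs are memoized per (fs, f_hp, f_lp).
.design_cache <- new.env(parent = emptyenv())

#' Design the pulse-wave FIR band-pass filter
#'
#' Linear-phase windowed-sinc (Hamming) band-pass with transition width
#' <= 0.35 Hz. The ideal cutoffs are tuned iteratively so the measured
#' -3 dB points land on `f_hp` and `f_lp` (within 0.02 Hz, well inside the
#' +/- 0.1 Hz contract). Defaults are the device's digital pre-processing
#' band: 0.7-9.5 Hz.
#'
#' @param fs Sampling rate (Hz).
#' @param f_hp High-pass (lower) -3 dB edge (Hz).
#' @param f_lp Low-pass (upper) -3 dB edge (Hz).
#' @param transition Maximum transition width (Hz).
#' @return An object of class `fir_design`: list with coefficients `h`,
#'   `fs`, requested edges, tap count and the measured -3 dB edges.
#' @export
design_bpf <- function(fs, f_hp = 0.7, f_lp = 9.5, transition = 0.35) {
  if (!(f_hp > 0 && f_hp < f_lp && f_lp < fs / 2)) {
    abort_config("need 0 < f_hp < f_lp < fs/2")
  }
  key <- paste(fs, f_hp, f_lp, transition, sep = "|")
  if (!is.null(.design_cache[[key]])) return(.design_cache[[key]])
  n_taps <- ceiling(3.3 * fs / transition)
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  c1 <- f_hp
  c2 <- f_lp
  edge <- function(h, target, rising) {
    # locate |H| = 1/sqrt(2) near `target`
    span <- max(0.5, transition * 2)
    lo <- max(1e-4, target - span)
    hi <- min(fs / 2 - 1e-4, target + span)
    fgrid <- seq(lo, hi, length.out = 200)
    mag <- fir_response(h, fgrid, fs) - 1 / sqrt(2)
    sgn <- sign(mag)
    flip <- which(sgn[-1] != sgn[-length(sgn)])
    if (!length(flip)) return(NA_real_)
    i <- if (rising) flip[1] else flip[length(flip)]
    stats::uniroot(function(f) fir_response(h, f, fs) - 1 / sqrt(2),
                   c(fgrid[i], fgrid[i + 1]), tol = 1e-7)$root
  }
  for (iter in 1:8) {
    h <- fir_bandpass_proto(n_taps, c1, c2, fs)
    e1 <- edge(h, f_hp, rising = TRUE)
    e2 <- edge(h, f_lp, rising = FALSE)
    if (is.na(e1) || is.na(e2)) abort_config("band-pass design infeasible for this fs")
    if (abs(e1 - f_hp) < 5e-3 && abs(e2 - f_lp) < 5e-3) break
    c1 <- c1 + (f_hp - e1)
    c2 <- c2 + (f_lp - e2)
    if (c1 <= 0 || c2 >= fs / 2) abort_config("band-pass design infeasible for this fs")
  }
  out <- structure(
    list(h = h, fs = fs, f_hp = f_hp, f_lp = f_lp, n_taps = n_taps,
         edges = c(lower = e1, upper = e2)),
    class = "fir_design"
  )
  .design_cache[[key]] <- out
  out
}

#' Apply a band-pass design to a signal
#'
#' Zero-phase (group-delay compensated) filtering.
#'
#' @param signal A [pulse_signal()].
#' @param design A `fir_design` from [design_bpf()]; defaults to the
#'   0.7-9.5 Hz pulse band at the signal's rate.
#' @return The filtered [pulse_signal()].
#' @export
bpf_apply <- function(signal, design = design_bpf(signal$fs)) {
  stopifnot(inherits(signal, "pulse_signal"), inherits(design, "fir_design"))
  if (!isTRUE(all.equal(design$fs, signal$fs))) {
    abort_config("filter design rate does not match the signal rate")
  }
  signal_with(signal, fir_apply(signal$samples, design$h))
}

#' Decimate a signal by an integer factor
#'
#' Anti-alias low-pass (windowed sinc, cutoff `0.4 * fs_target`, transition
#' `0.1 * fs_target`) followed by integer downsampling. Passband content at
#' or below the pulse band is preserved within 1%.
#'
#' @param signal A [pulse_signal()].
#' @param fs_target Target rate (Hz); must divide `signal$fs`.
#' @return The decimated [pulse_signal()].
#' @export
decimate <- function(signal, fs_target) {
  stopifnot(inherits(signal, "pulse_signal"))
  check_scalar(fs_target, "fs_target")
  factor <- signal$fs / fs_target
  if (abs(factor - round(factor)) > 1e-9) {
    abort_config(sprintf("fs_target (%g) must divide fs (%g)", fs_target,
                         signal$fs))
  }
  factor <- round(factor)
  if (factor == 1L) return(signal)
  n_taps <- ceiling(3.3 * signal$fs / (0.1 * fs_target))
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  h <- fir_lowpass(n_taps, 0.4 * fs_target, signal$fs)
  y <- fir_apply(signal$samples, h)
  pulse_signal(y[seq(1, length(y), by = factor)], fs = fs_target,
               unit = signal$unit, role = signal$role)
}

# Bilinear transform of an analog biquad (B2 s^2 + B1 s + B0) /
# (A2 s^2 + A1 s + A0) at rate fs (no pre-warping: all AFE corner
# frequencies are far below fs/2). Returns list(b, a) with a[1] = 1.
bilinear_biquad <- function(B, A, fs) {
  K <- 2 * fs
  b <- c(B[1] + B[2] * K + B[3] * K^2,
         2 * B[1] - 2 * B[3] * K^2,
         B[1] - B[2] * K + B[3] * K^2)
  a <- c(A[1] + A[2] * K + A[3] * K^2,
         2 * A[1] - 2 * A[3] * K^2,
         A[1] - A[2] * K + A[3] * K^2)
  list(b = b / a[1], a = a / a[1])
}

# Direct-form IIR filtering via stats::filter (C speed): MA part as
# convolution on a zero-prepadded input, then the AR recursion.
iir_apply <- function(x, b, a) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[-seq_len(nb - 1)]
  if (length(a) > 1L) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}
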