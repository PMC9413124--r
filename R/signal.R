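# Uniformly sampled signal container shared by all modules.

SIGNAL_ROLES <- c("piezo_proximal", "piezo_distal", "ppg", "generic")

#' Uniformly sampled signal
#'
#' @param samples Numeric vector of samples (no missing values).
#' @param fs Sampling rate (Hz).
#' @param unit Unit label for the samples.
#' @param role Channel role: `"piezo_proximal"`, `"piezo_distal"`, `"ppg"`
#'   or `"generic"`.
#' @return An object of class `pulse_signal`.
#' @export
pulse_signal <- function(samples, fs, unit = "a.u.", role = "generic") {
  if (!is.numeric(samples) || length(samples) < 1L) {
    abort_invalid("'samples' must be a non-empty numeric vector")
  }
  if (anyNA(samples)) abort_invalid("'samples' must not contain missing values")
  check_scalar(fs, "fs")
  role <- match.arg(role, SIGNAL_ROLES)
  structure(list(samples = as.numeric(samples), fs = fs, unit = unit,
                 role = role),
            class = "pulse_signal")
}

#' @export
print.pulse_signal <- function(x, ...) {
  cat(sprintf("<pulse_signal %s: %d samples @ %g Hz (%.2f s), unit %s>\n",
              x$role, length(x$samples), x$fs, length(x$samples) / x$fs,
              x$unit))
  invisible(x)
}

signal_duration <- function(x) length(x$samples) / x$fs

signal_times <- function(x) (seq_along(x$samples) - 1) / x$fs

# Replace the samples of a signal, keeping metadata.
signal_with <- function(x, samples, unit = x$unit) {
  pulse_signal(samples, fs = x$fs, unit = unit, role = x$role)
}
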