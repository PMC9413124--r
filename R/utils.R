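# Internal helpers: unit conversion, error conditions, seeded evaluation.

# 1 mmHg in pascal; used at every public mmHg interface. All internal
# physics is SI (Pa, m, s, kg/m^3).
MMHG_PA <- 133.322

mmhg_to_pa <- function(x) x * MMHG_PA
pa_to_mmhg <- function(x) x / MMHG_PA

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pulsebp_error", "error", "condition")))
}
abort_invalid <- function(msg) abort(msg, "pulsebp_invalid_input")
abort_config <- function(msg) abort(msg, "pulsebp_config_error")
abort_calibration <- function(msg) abort(msg, "pulsebp_calibration_error")
abort_data <- function(msg) abort(msg, "pulsebp_data_error")
abort_usage <- function(msg) abort(msg, "pulsebp_usage_error")
abort_format <- function(msg) abort(msg, c("pulsebp_format_error", "pulsebp_data_error"))
abort_simulation <- function(msg) abort(msg, "pulsebp_simulation_error")

check_scalar <- function(x, name, positive = TRUE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_invalid(sprintf("'%s' must be a single numeric value", name))
  }
  if (finite && !is.finite(x)) abort_invalid(sprintf("'%s' must be finite", name))
  if (positive && x <= 0) abort_invalid(sprintf("'%s' must be > 0 (got %g)", name, x))
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Polynomial rolling hash of a string; used only to fingerprint
# configurations in logs (not cryptographic).
string_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
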