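# Shared fixtures. Heavy simulations are memoized so several test files can
# reuse them within one run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# A fixed mid-range subject used across unit tests.
fix_profile <- function(deltaD = 1.5e-4, heart_rate = 72, seed = 101L) {
  subject_profile(
    subject_id = "T001", true_map = 95, heart_rate = heart_rate,
    arterial = arterial_state(Dd = 2.5e-3, deltaD = deltaD, h = 3e-4),
    stiffness = stiffness_params(E0 = 70e3, xi = 0.016),
    optics = optics_params(), seed = seed
  )
}

# One noiseless and one 20 dB session for the fixed subject (25 s).
fix_session <- function(snr_db = Inf) {
  key <- paste0("session_", snr_db)
  memo(key, simulate_session(fix_profile(), session = 1L, duration = 25,
                             snr_db = snr_db, session_bp_sd = 0))
}

# Clean filtered pulse train at the working rate, for detector tests.
fix_filtered_piezo <- function(snr_db = Inf) {
  key <- paste0("filtered_", snr_db)
  memo(key, {
    sim <- fix_session(snr_db)
    sig <- decimate(sim$record$signals$piezo_proximal, 500)
    bpf_apply(sig, design_bpf(500))
  })
}

expect_rel_equal <- function(object, expected, tol = 1e-9) {
  expect_true(abs(object - expected) <= tol * max(1, abs(expected)),
              label = sprintf("%.12g vs %.12g (rel tol %g)", object,
                              expected, tol))
}
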