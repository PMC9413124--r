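test_that("make_cohort is deterministic and honours its invariants", {
  c1 <- make_cohort(20, seed = 42)
  c2 <- make_cohort(20, seed = 42)
  expect_identical(c1, c2)
  for (p in c1) {
    expect_true(p$true_sbp > p$true_map && p$true_map > p$true_dbp &&
                  p$true_dbp > 0)
    expect_equal(p$true_dbp, p$stiffness$k * p$true_map)
    expect_equal(p$true_sbp, p$true_map + (1 - p$stiffness$k) * p$true_dbp)
    # generator wave speed comes from the pressure-dependent modulus
    expect_rel_equal(
      p$true_pwv,
      mk_pwv(p$arterial, youngs_modulus(p$stiffness, p$true_map)))
    expect_true(p$arterial$deltaD / p$arterial$Dd < 0.10)
  }
  expect_error(make_cohort(0), class = "pulsebp_config_error")
  expect_error(make_cohort(5, ranges = list(map_mmhg = c(120, 70))),
               class = "pulsebp_config_error")
  expect_error(make_cohort(5, ranges = list(bogus = c(1, 2))),
               class = "pulsebp_config_error")
})

test_that("cohort MAP marginal matches the configured uniform range", {
  big <- make_cohort(1000, seed = 9)
  maps <- vapply(big, `[[`, 0, "true_map")
  ks <- suppressWarnings(stats::ks.test(maps, "punif", 70, 120))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(maps >= 70 & maps <= 120))
})

test_that("gen_pulse_pair delays the distal channel by the stated transit time", {
  prof <- fix_profile()
  pair <- gen_pulse_pair(prof, duration = 10, fs = 5000,
                         sensor_distance = 0.02)
  expect_equal(pair$true_ptt, 0.02 / pair$true_pwv)
  # cross-correlation lag of the clean channels equals true_ptt within 1/fs
  x1 <- pair$proximal$samples
  x2 <- pair$distal$samples
  lags <- 0:60
  cc <- vapply(lags, function(l) {
    n <- length(x1)
    sum(x1[1:(n - l)] * x2[(1 + l):n])
  }, numeric(1))
  lag_hat <- lags[which.max(cc)] / 5000
  expect_lt(abs(lag_hat - pair$true_ptt), 1 / 5000)
  # zero distance: identical channels, zero delay
  pair0 <- gen_pulse_pair(prof, duration = 5, fs = 5000, sensor_distance = 0)
  expect_equal(pair0$true_ptt, 0)
  expect_identical(pair0$proximal$samples, pair0$distal$samples)
  # beat count ~ duration * hr / 60
  expect_lt(abs(length(pair$onsets) - 10 * prof$heart_rate / 60), 2)
  expect_error(gen_pulse_pair(prof, duration = 2), class = "pulsebp_invalid_input")
  expect_error(gen_pulse_pair(prof, duration = 10, fs = 100),
               class = "pulsebp_invalid_input")
})

test_that("chamber_response is the linear adiabatic compression law", {
  ch <- chamber_params()
  x <- pulse_signal(rep(0, 100), 1000)
  expect_equal(chamber_response(x, ch)$samples, rep(0, 100))
  # frozen: gamma=1.4, PA=101325 Pa, (A/V) x = 1e-4 -> |Pa| = 14.1855 Pa
  xs <- pulse_signal(rep(1e-4 * ch$V / ch$A, 10), 1000)
  expect_equal(abs(chamber_response(xs, ch)$samples),
               rep(14.18550, 10), tolerance = 1e-5)
  # linearity
  x1 <- pulse_signal(sin(1:50 / 5) * 1e-5, 1000)
  x2 <- signal_with(x1, 2 * x1$samples)
  expect_equal(chamber_response(x2, ch)$samples,
               2 * chamber_response(x1, ch)$samples)
  # volume bound violation
  huge <- pulse_signal(rep(ch$V / ch$A, 10), 1000)
  expect_error(chamber_response(huge, ch), class = "pulsebp_simulation_error")
})

test_that("gen_ppg follows the Beer-Lambert intensity swing", {
  prof <- fix_profile(deltaD = 1.5e-4)
  raw <- gen_ppg(prof, duration = 10, fs = 100, quantize = FALSE)
  # clean max/min over the record equals exp(alpha * deltaD) = exp(0.075)
  ratio <- max(raw$samples) / min(raw$samples)
  expect_equal(ratio, exp(500 * 1.5e-4), tolerance = 1e-3)
  expect_equal(exp(0.075), 1.0779, tolerance = 1e-4)  # the frozen value
  tr <- ppg_truth(prof)
  expect_rel_equal(tr$pir, exp(0.075), tol = 1e-12)
  # degenerate artery: constant amplitude, PIR = 1
  prof0 <- fix_profile(deltaD = 0)
  raw0 <- gen_ppg(prof0, duration = 6, fs = 100, quantize = FALSE)
  expect_lt(diff(range(raw0$samples)), 1e-9)
  # intensities bounded in (0, I0]; quantization keeps the ADC grid
  q <- gen_ppg(prof, duration = 6, fs = 100)
  expect_true(all(q$samples > 0 & q$samples <= prof$optics$I0))
  expect_true(all(q$samples == round(q$samples)))
  expect_true(all(q$samples < 2^18))
})

test_that("add_noise hits the requested SNR and is seed-reproducible", {
  set.seed(1)
  x <- pulse_signal(sin(2 * pi * 2 * (0:999999) / 1000), 1000)
  y <- add_noise(x, 20, seed = 3)
  snr_emp <- 10 * log10(stats::var(x$samples) /
                          stats::var(y$samples - x$samples))
  expect_lt(abs(snr_emp - 20), 0.5)
  y2 <- add_noise(x, 20, seed = 3)
  expect_identical(y$samples, y2$samples)
  expect_identical(add_noise(x, Inf, seed = 1)$samples, x$samples)
})

test_that("simulate_session is reproducible and internally consistent", {
  prof <- fix_profile()
  s1 <- simulate_session(prof, 2, duration = 12, snr_db = 20)
  s2 <- simulate_session(prof, 2, duration = 12, snr_db = 20)
  expect_identical(s1$record$signals$piezo_proximal$samples,
                   s2$record$signals$piezo_proximal$samples)
  expect_identical(s1$truth, s2$truth)
  # session truth follows the tracking decomposition
  expect_equal(s1$truth$dbp, s1$truth$map * prof$stiffness$k)
  expect_equal(s1$truth$sbp,
               s1$truth$map + (1 - prof$stiffness$k) * s1$truth$dbp)
  expect_equal(s1$truth$ptt, 0.02 / s1$truth$pwv)
})
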