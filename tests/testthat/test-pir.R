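test_that("extract_ih_il recovers the generator's intensity extrema", {
  sim <- fix_session(Inf)
  pm <- extract_ih_il(sim$record$signals$ppg)
  tr <- ppg_truth(fix_profile())
  ok <- pm$valid
  expect_gt(sum(ok), 10)
  # within a few ADC counts of the continuous truth (quantization +
  # sampling refinement)
  expect_lt(stats::median(abs(pm$ih[ok] - tr$ih)), 3)
  expect_lt(stats::median(abs(pm$il[ok] - tr$il)), 3)
  expect_lt(abs(pm$pir_median - tr$pir), 1e-3)
  expect_true(all(pm$pir[ok] >= 1))
})

test_that("extract_ih_il flags saturated cycles and degenerate input", {
  sim <- fix_session(Inf)
  ppg <- sim$record$signals$ppg
  sat <- ppg
  # saturate one mid-record cycle
  i0 <- round(12 * ppg$fs):round(12.5 * ppg$fs)
  sat$samples[i0] <- 2^18 - 1
  pm <- extract_ih_il(sat)
  expect_true(any(!pm$valid))
  expect_gt(sum(pm$valid), 10)
  # constant signal with supplied beats: ih = il, pir = 1
  const <- pulse_signal(rep(1000, 1200), 100, role = "ppg")
  beats <- beat_features(seq(1, 10, by = 0.8), seq(1.1, 10.1, by = 0.8),
                         rep(1, 12), rep(TRUE, 12), fs = 100)
  pmc <- extract_ih_il(const, beats)
  expect_true(all(pmc$ih == pmc$il))
  expect_true(all(pmc$pir == 1))
  expect_error(extract_ih_il(pulse_signal(c(-1, rep(1, 400)), 100)),
               class = "pulsebp_data_error")
})

test_that("ppg_norm implements both readings of the normalization", {
  expect_equal(ppg_norm(10, 10), 1.0)
  expect_equal(ppg_norm(1, 50), 0.0)
  expect_equal(ppg_norm(exp(2), exp(4)), 0.5)
  expect_error(ppg_norm(10, 0.5), class = "pulsebp_data_error")
  expect_error(ppg_norm(0, 10), class = "pulsebp_data_error")
  # ratio reading goes negative for AC < DC (why it is not the default)
  expect_equal(ppg_norm(exp(2), exp(4), reading = "ratio"), -2)
})

test_that("delta_d_from_pir and alpha_calibrate are exact inverses", {
  expect_equal(delta_d_from_pir(1, 500), 0)
  expect_equal(delta_d_from_pir(exp(0.075), 500), 1.5e-4, tolerance = 1e-12)
  expect_equal(alpha_calibrate(exp(0.075), 1.5e-4), 500, tolerance = 1e-9)
  for (pir in c(1.01, 1.05, 1.2)) {
    a <- alpha_calibrate(pir, 2e-4)
    expect_rel_equal(delta_d_from_pir(pir, a), 2e-4, tol = 1e-12)
  }
  # monotone in pir; inverse scaling in the reference
  expect_true(all(diff(delta_d_from_pir(c(1.01, 1.05, 1.1), 500)) > 0))
  expect_rel_equal(alpha_calibrate(1.1, 2e-4), 2 * alpha_calibrate(1.1, 4e-4))
  expect_error(delta_d_from_pir(0.99, 500), class = "pulsebp_data_error")
  expect_error(alpha_calibrate(1.0, 1e-4), class = "pulsebp_calibration_error")
})

test_that("fit_diameter_model recovers exact lines and guards degeneracy", {
  x <- seq(0.5, 0.9, length.out = 10)
  y <- 2e-3 + 1.5e-3 * x
  m <- fit_diameter_model(x, y)
  expect_equal(m$slope, 1.5e-3, tolerance = 1e-9)
  expect_equal(m$intercept, 2e-3, tolerance = 1e-9)
  expect_equal(m$fit_r2, 1, tolerance = 1e-9)
  pred <- predict_dd(m, 0.7)
  expect_equal(as.numeric(pred), 2e-3 + 1.5e-3 * 0.7, tolerance = 1e-12)
  expect_false(attr(pred, "extrapolated"))
  expect_warning(p2 <- predict_dd(m, 2), "range")
  expect_true(attr(p2, "extrapolated"))
  expect_error(fit_diameter_model(c(1, 1, 1), c(1, 2, 3) * 1e-3),
               class = "pulsebp_calibration_error")
  expect_error(fit_diameter_model(c(1, 2), c(1, 2) * 1e-3),
               class = "pulsebp_calibration_error")
})

test_that("the diameter model predicts cohort diameters under a monotone optics map", {
  # fixed fractional excursion makes the optics map monotone in Dd
  ranges <- cohort_ranges()
  ranges$delta_ratio <- c(0.06, 0.06)
  cohort <- make_cohort(50, seed = 21, ranges = ranges)
  obs <- t(vapply(cohort, function(p) {
    pm <- extract_ih_il(gen_ppg(p, duration = 12, fs = 100))
    c(pn = pm$ppg_norm, dd = p$arterial$Dd)
  }, numeric(2)))
  m <- fit_diameter_model(obs[, "pn"], obs[, "dd"])
  pred <- suppressWarnings(predict_dd(m, obs[, "pn"]))
  rms <- sqrt(mean((as.numeric(pred) - obs[, "dd"])^2))
  expect_lt(rms / mean(obs[, "dd"]), 0.05)
})

test_that("optics round trip recovers deltaD within quantization error", {
  sim <- fix_session(Inf)
  pm <- extract_ih_il(sim$record$signals$ppg)
  dd_est <- delta_d_from_pir(pm$pir_median, 500)
  expect_lt(abs(dd_est - 1.5e-4), 2e-6)  # ~ a few 18-bit counts in ln-space
})

test_that("session PIR median is order-invariant and outlier-robust", {
  sim <- fix_session(Inf)
  pm <- extract_ih_il(sim$record$signals$ppg)
  ok <- pm$valid & pm$pir >= 1
  med <- stats::median(pm$pir[ok])
  expect_equal(stats::median(sample(pm$pir[ok])), med)
  perturbed <- c(pm$pir[ok], 5)  # one wild beat
  expect_lt(abs(stats::median(perturbed) - med), 0.01)
})
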