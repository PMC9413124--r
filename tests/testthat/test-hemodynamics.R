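test_that("pwv_from_ptt divides distance by transit time and rejects bad input", {
  expect_equal(pwv_from_ptt(0.02, 0.004), 5.0)
  expect_equal(pwv_from_ptt(1, 1), 1.0)
  expect_error(pwv_from_ptt(0.02, 0), class = "pulsebp_invalid_input")
  expect_error(pwv_from_ptt(0, 0.004), class = "pulsebp_invalid_input")
})

test_that("mk_pwv follows the Moens-Korteweg relation", {
  st <- arterial_state(Dd = 2.5e-3, h = 3e-4)
  # terms cancel when E = rho * D / h
  expect_rel_equal(mk_pwv(st, st$rho_blood * st$D / st$h), 1.0)
  # frozen hand-arithmetic value: sqrt(5e5 * 3e-4 / (2.5e-3 * 1060))
  expect_equal(mk_pwv(st, 500e3), 7.523548, tolerance = 1e-6)
  # scaling law
  expect_rel_equal(mk_pwv(st, 2 * 500e3), sqrt(2) * mk_pwv(st, 500e3))
  expect_error(mk_pwv(st, -1), class = "pulsebp_invalid_input")
})

test_that("youngs_modulus is E0 * exp(xi * P)", {
  p <- stiffness_params(E0 = 100e3, xi = 0.016)
  expect_equal(youngs_modulus(p, 0), 100e3)
  expect_equal(youngs_modulus(stiffness_params(E0 = 100e3, xi = 0), 137),
               100e3)
  # frozen: 100 kPa * exp(1.6)
  expect_equal(youngs_modulus(p, 100), 100e3 * exp(1.6))
  expect_true(all(diff(youngs_modulus(p, seq(60, 180, 10))) > 0))
})

test_that("mk_pressure is the exact inverse of mk_pwv o youngs_modulus", {
  st <- arterial_state(Dd = 2.5e-3, h = 3e-4)
  pars <- stiffness_params(E0 = 70e3, xi = 0.016)
  for (P in seq(60, 180, by = 10)) {
    back <- mk_pressure(st, pars, mk_pwv(st, youngs_modulus(pars, P)))
    expect_rel_equal(back, P, tol = 1e-9)
  }
  # pwv^2 = h*E0/(rho*D) makes the log argument 1
  pwv0 <- sqrt(st$h * pars$E0 / (st$rho_blood * st$D))
  expect_equal(mk_pressure(st, pars, pwv0), 0, tolerance = 1e-12)
  # consistency with the mk_pwv frozen example: invert back to E = 500 kPa
  P_from_E <- log(500e3 / pars$E0) / pars$xi
  expect_rel_equal(mk_pressure(st, pars, mk_pwv(st, 500e3)), P_from_E)
  expect_error(mk_pressure(st, stiffness_params(E0 = 1, xi = 0), 5),
               class = "pulsebp_invalid_input")
})

test_that("regression_fit recovers exact and noisy coefficients", {
  ptt <- seq(0.002, 0.01, length.out = 20)
  bp <- -50 * log(ptt) + 0
  cf <- regression_fit(ptt, bp)
  expect_equal(cf$K1, -50, tolerance = 1e-9)
  expect_equal(cf$K2, 0, tolerance = 1e-7)
  # two points: exact interpolation
  cf2 <- regression_fit(c(0.003, 0.006), c(120, 80))
  expect_equal(regression_predict(cf2, 0.003), 120, tolerance = 1e-9)
  expect_equal(regression_predict(cf2, 0.006), 80, tolerance = 1e-9)
  # matches lm() on random data (definitional oracle)
  set.seed(5)
  x <- runif(50, 0.002, 0.01)
  y <- -120 * log(x) + 30 + rnorm(50, 0, 3)
  ref <- stats::lm(y ~ log(x))
  cf3 <- regression_fit(x, y)
  expect_equal(cf3$K1, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(cf3$K2, unname(coef(ref)[1]), tolerance = 1e-10)
  # noisy recovery within 3 standard errors
  se <- summary(ref)$coefficients[2, 2]
  expect_lt(abs(cf3$K1 - (-120)), 3 * se)
  expect_error(regression_fit(0.004, 100), class = "pulsebp_calibration_error")
  expect_error(regression_fit(c(0.004, 0.004), c(100, 110)),
               class = "pulsebp_calibration_error")
})

test_that("regression_fit is unbiased over Monte-Carlo replicates", {
  set.seed(77)
  k1s <- replicate(1000, {
    x <- runif(12, 0.002, 0.01)
    y <- -100 * log(x) + 10 + rnorm(12, 0, 4)
    regression_fit(x, y)$K1
  })
  expect_lt(abs(mean(k1s) - (-100)), 3 * sd(k1s) / sqrt(1000))
})

test_that("regression_predict evaluates K1 ln(ptt) + K2", {
  cf <- regression_coeffs(-50, 0)
  expect_equal(regression_predict(regression_coeffs(-3, 42), 1), 42)
  expect_equal(regression_predict(cf, exp(-2)), 100)
  expect_error(regression_predict(cf, 0), class = "pulsebp_invalid_input")
})

test_that("pulse_pressure implements the Bramwell-Hill pulse-pressure form", {
  st0 <- arterial_state(Dd = 2.5e-3, deltaD = 0, h = 3e-4)
  expect_equal(pulse_pressure(st0, 5), 0)
  # frozen: 1060 * 25 * (2*0.05 + 0.05^2) = 2716.25 Pa = 20.374 mmHg
  st <- arterial_state(Dd = 2.5e-3, deltaD = 0.05 * 2.5e-3, h = 3e-4)
  expect_equal(pulse_pressure(st, 5), 2716.25 / 133.322, tolerance = 1e-9)
  # 2x + x^2 = 1 at x = sqrt(2) - 1: output in Pa equals rho exactly
  stx <- suppressWarnings(
    arterial_state(Dd = 1e-3, deltaD = (sqrt(2) - 1) * 1e-3, h = 3e-4))
  expect_rel_equal(pulse_pressure(stx, 1) * 133.322, 1060, tol = 1e-12)
})

test_that("map_p_beta and beta_calibrate are exact inverses", {
  st <- arterial_state(Dd = 2.5e-3, h = 3e-4)
  expect_equal(map_p_beta(st, 4, 0), 0)
  # frozen: 2 * 1060 * 25 / 4 = 13250 Pa = 99.38 mmHg
  expect_equal(map_p_beta(st, 4, 5), 13250 / 133.322, tolerance = 1e-9)
  expect_rel_equal(map_p_beta(st, 8, 5), map_p_beta(st, 4, 5) / 2)
  b <- beta_calibrate(st, 5, 13250 / 133.322)
  expect_equal(b, 4, tolerance = 1e-9)
  for (m in c(70, 95, 120)) {
    bb <- beta_calibrate(st, 6, m)
    expect_rel_equal(map_p_beta(st, bb, 6), m, tol = 1e-12)
  }
  # beta strictly decreasing in map_ref
  expect_true(all(diff(vapply(c(70, 90, 110, 130),
                              function(m) beta_calibrate(st, 5, m),
                              numeric(1))) < 0))
  expect_error(map_p_beta(st, -1, 5), class = "pulsebp_invalid_input")
  expect_error(beta_calibrate(st, 0, 90), class = "pulsebp_calibration_error")
})

test_that("track_sbp_dbp implements the printed tracking decomposition", {
  est <- track_sbp_dbp(100, k = 0.76)
  expect_equal(est$dbp, 76)
  expect_equal(est$sbp, 118.24)
  expect_equal(est$map, 100)
  # degenerate k = 1 collapses the decomposition
  est1 <- track_sbp_dbp(100, k = 1)
  expect_equal(est1$dbp, 100)
  expect_equal(est1$sbp, 100)
  # DBP/MAP = k identically; ordering invariant over a grid
  for (map in c(40, 80, 120, 200)) {
    for (k in c(0.2, 0.5, 0.76, 1)) {
      e <- track_sbp_dbp(map, k = k)
      expect_equal(e$dbp / map, k)
      expect_true(e$sbp >= e$map && e$map >= e$dbp)
      expect_true(e$valid)
    }
  }
  expect_error(track_sbp_dbp(100, k = 1.2), class = "pulsebp_invalid_input")
  expect_error(track_sbp_dbp(100, k = 0), class = "pulsebp_invalid_input")
  # pp variant consumes the measured pulse pressure
  ep <- track_sbp_dbp(100, pp = 40, k = 0.76, variant = "pp")
  expect_equal(ep$sbp, 100 + 0.24 * 40)
})

test_that("bp_estimate flags ordering violations instead of failing", {
  bad <- bp_estimate(sbp = 100, dbp = 90, map = 110, method = "regression")
  expect_false(bad$valid)
  ok <- bp_estimate(sbp = 120, dbp = 80, map = 93)
  expect_true(ok$valid)
})

test_that("arterial_state enforces geometry invariants", {
  st <- arterial_state(Dd = 2.5e-3, deltaD = 1e-4, h = 3e-4)
  expect_equal(st$Ds, st$Dd + st$deltaD)
  expect_error(arterial_state(Dd = -1, h = 3e-4),
               class = "pulsebp_invalid_input")
  expect_error(arterial_state(Dd = 2.5e-3, deltaD = -1e-5, h = 3e-4),
               class = "pulsebp_invalid_input")
  expect_warning(arterial_state(Dd = 2.5e-3, deltaD = 0.3e-3, h = 3e-4),
                 "10%")
})
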