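test_that("derivative Tm calling recovers logistic midpoints at 1-degree sampling", {
  for (tm in c(55, 70, 90)) {
    curve <- sim_melt_curve(tm, noise_sd = 0, seed = 1)
    expect_lte(abs(tm_by_derivative(curve) - tm), 0.1 + 1e-9)
  }
  # falling transitions (BCM shifts down) are located equally well
  down <- sim_melt_curve(62, assay = "nanodsf_bcm", noise_sd = 0, seed = 1)
  expect_lte(abs(tm_by_derivative(down) - 62), 0.1 + 1e-9)
})

test_that("Tm calling is invariant to affine rescaling of the signal", {
  curve <- sim_melt_curve(68, noise_sd = 0, seed = 2)
  tm1 <- tm_by_derivative(curve)
  scaled <- curve
  scaled$signal <- -3.7 * scaled$signal + 1200
  expect_equal(tm_by_derivative(scaled), tm1)
})

test_that("traces without a transition are rejected", {
  linear <- melt_curve(25:95, 5 + 0.3 * (25:95), assay = "cd_mre")
  expect_error(tm_by_derivative(linear), "transition")
  drifty <- sim_melt_curve(70, amplitude = 0, baseline_drift = 12,
                           noise_sd = 0, seed = 3)
  expect_error(tm_by_derivative(drifty), "transition")
})

test_that("threshold crossing matches linear and analytic-logistic cases", {
  # linear trace crossing a flat threshold at exactly 80 C
  tt <- seq(25, 95, 1)
  lin <- melt_curve(tt, (tt - 80) * 2, assay = "sls_counts")
  # flat line 110 units above the starting signal, i.e. at zero
  spec0 <- threshold_spec(intercept_fraction = 1, endpoint_magnitude = 110,
                          drift_slope = 0)
  expect_equal(t_by_threshold(lin, spec0), 80, tolerance = 1e-6)
  # SLS preset: intercept is 20% of the 60,000-count endpoint
  pre <- threshold_spec("sls")
  expect_equal(pre$intercept_fraction * pre$endpoint_magnitude, 12000)
  sls <- sim_melt_curve(85, assay = "sls_counts", amplitude = 60000,
                        noise_sd = 0, seed = 1)
  onset <- t_by_threshold(sls, pre)
  analytic <- 85 + 2 * log(0.2 / 0.8)  # logistic crosses 20% here
  expect_lt(abs(onset - analytic), 0.5)
  # nanoDSF presets encode the stated endpoint fractions
  n40 <- threshold_spec("nanodsf_i53_40")
  expect_equal(n40$intercept_fraction, 0.5)
  expect_equal(n40$endpoint_magnitude, -4.5)
  n50 <- threshold_spec("nanodsf_i53_50")
  expect_equal(n50$intercept_fraction * n50$endpoint_magnitude, 0.2 * -14.2)
  bcm <- sim_melt_curve(75, assay = "nanodsf_bcm", amplitude = -4.5,
                        noise_sd = 0, seed = 1)
  onset_bcm <- t_by_threshold(bcm, n40)
  expect_lt(abs(onset_bcm - 75), 0.5)  # 50% of the shift is the midpoint
  # the CD preset demands an explicit system-specific endpoint
  expect_error(threshold_spec("cd_i53_50"), "endpoint")
  # no crossing in range
  flat <- melt_curve(tt, rep(0, length(tt)), assay = "sls_counts")
  expect_error(t_by_threshold(flat, pre), "never crosses")
})

test_that("threshold calling is deterministic and drift-aware", {
  sls <- sim_melt_curve(85, assay = "sls_counts", amplitude = 60000,
                        baseline_drift = 40, noise_sd = 0, seed = 1)
  drift <- baseline_drift(sls)
  expect_equal(drift, 40, tolerance = 0.5)
  spec <- threshold_spec("sls", drift_slope = drift)
  t1 <- t_by_threshold(sls, spec)
  t2 <- t_by_threshold(sls, spec)
  expect_identical(t1, t2)
  # the drift-matched line still finds an onset below the midpoint
  expect_lt(t1, 85)
})

test_that("initial rates are window least squares, relative to a control", {
  tr <- tibble::tibble(time_s = 0:300, a339 = 1 - 0.001 * (0:300))
  ir <- initial_rate(tr)
  expect_equal(ir$slope, -0.001, tolerance = 1e-12)
  expect_equal(initial_rate(tr, control_slope = -0.001)$relative, 1)
  expect_equal(initial_rate(tr, control_slope = -0.002)$relative, 0.5)
  flat <- tibble::tibble(time_s = 0:300, a339 = rep(0.8, 301))
  expect_equal(initial_rate(flat, control_slope = -0.002)$relative, 0)
  expect_error(initial_rate(tr[tr$time_s < 100, ]), "window")
})
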