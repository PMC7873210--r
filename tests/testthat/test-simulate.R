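test_that("simulated datasets are deterministic under a seed", {
  a <- sim_cooperativity_dataset(3.6, noise_cv = 0.05, seed = 123)
  b <- sim_cooperativity_dataset(3.6, noise_cv = 0.05, seed = 123)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_peak_areas(a, f1)
  write_peak_areas(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  c <- sim_cooperativity_dataset(3.6, noise_cv = 0.05, seed = 124)
  expect_false(identical(a$high_mw_area, c$high_mw_area))
})

test_that("the cooperativity design matches the reference experiment layout", {
  dat <- sim_cooperativity_dataset(3.6, seed = 5)
  asm <- dat[dat$injection_type == "assembly" & !dat$is_reference, ]
  # 2 series x 8 stoichiometries x 3 replicates
  expect_equal(nrow(asm), 2 * 8 * 3)
  expect_setequal(unique(asm$series_id), c("vary_t", "vary_p"))
  expect_equal(sort(unique(asm$t0_uM[asm$series_id == "vary_t"])),
               c(12.5, 25, 37.5, 50, 75, 100, 125, 150))
  expect_true(all(asm$p0_uM[asm$series_id == "vary_t"] == 50))
  expect_equal(sum(dat$is_reference & dat$injection_type == "assembly"), 6)
  expect_equal(sum(dat$injection_type == "component_t"), 3)
})

test_that("noiseless synthetic areas equal the model predictions after normalization", {
  dat <- sim_cooperativity_dataset(3.7, noise_cv = 0, seed = 6)
  nm <- normalize_peak_areas(dat)
  obs <- nm[!nm$is_reference, ]
  st <- solve_equilibrium(dplyr::distinct(obs[, c("t0_uM", "p0_uM")]), 3.7,
                          species_table("inclusive"))
  sg <- predict_normalized_signals(st)
  key_obs <- paste(obs$t0_uM, obs$p0_uM)
  key_mod <- paste(sg$t0_uM, sg$p0_uM)
  expect_equal(obs$high_norm, sg$high_signal[match(key_obs, key_mod)],
               tolerance = 1e-9)
  expect_equal(obs$low_norm, sg$low_signal[match(key_obs, key_mod)],
               tolerance = 1e-9)
})

test_that("the full synthetic pipeline round-trips the generating energy", {
  dat <- dplyr::bind_rows(
    sim_cooperativity_dataset(4.0, noise_cv = 0, seed = 21),
    sim_equimolar_series(4.0, noise_cv = 0, seed = 22))
  fit <- fit_dgcon(normalize_peak_areas(dat), dg_scan = seq(3.7, 4.3, 0.01))
  expect_equal(fit$dg_best, 4.0, tolerance = 1e-9)
})

test_that("equimolar series put assembly efficiency in the usable Hill band or fail loudly", {
  # monotone theta across the transition
  dat <- sim_equimolar_series(3.6, noise_cv = 0, seed = 31)
  nm <- normalize_peak_areas(dat)
  mf <- mass_fraction_from_peaks(nm[!nm$is_reference, ], signal_factors())
  agg <- dplyr::summarise(dplyr::group_by(mf, t0_uM),
                          theta = mean(theta), .groups = "drop")
  agg <- agg[order(agg$t0_uM), ]
  expect_true(all(diff(agg$theta) > 0))
  h <- hill_analysis(nm[!nm$is_reference, ], signal_factors())
  expect_gt(h$hill_coefficient, 1)
  # far below the pseudo-critical concentration everything is unassembled
  low <- sim_equimolar_series(3.6, totals = c(0.01, 0.02, 0.05),
                              noise_cv = 0, seed = 32)
  nml <- normalize_peak_areas(low)
  expect_error(hill_analysis(nml[!nml$is_reference, ], signal_factors()),
               "theta")
})

test_that("simulated chromatograms round-trip their peak areas within 1%", {
  st <- predict_normalized_signals(
    solve_equilibrium(tibble::tibble(t0_uM = 50, p0_uM = 50), 3.6,
                      species_table("simplified")),
    factors = signal_factors(1, 0))
  tr <- sim_chromatogram(st)
  got <- integrate_chromatogram(tr)
  want <- attr(tr, "areas")
  expect_equal(got$area[got$peak == "assembled"], unname(want[["assembled"]]),
               tolerance = 0.01)
  expect_equal(got$area[got$peak == "components"], unname(want[["components"]]),
               tolerance = 0.01)
  # an unassembled state yields a single component peak
  free <- predict_normalized_signals(
    solve_equilibrium(tibble::tibble(t0_uM = 50, p0_uM = 50), 0,
                      species_table("simplified")),
    factors = signal_factors(1, 0))
  tr0 <- sim_chromatogram(free)
  got0 <- integrate_chromatogram(tr0)
  expect_lt(got0$area[got0$peak == "assembled"], 1e-6)
  expect_equal(got0$area[got0$peak == "components"], free$low_signal,
               tolerance = 0.01)
  # overlapping peaks are refused
  expect_error(sim_chromatogram(st, centers = c(assembled = 12, components = 12.5)),
               "separated")
})

test_that("simulated melt curves expose both caller paths", {
  expect_lte(abs(tm_by_derivative(sim_melt_curve(70, noise_sd = 0, seed = 1)) - 70),
             0.1 + 1e-9)
  sls <- sim_melt_curve(90, assay = "sls_counts", amplitude = 60000,
                        noise_sd = 0, seed = 2)
  onset <- t_by_threshold(sls, threshold_spec("sls"))
  expect_lt(onset, 90)  # onset precedes the midpoint
  expect_error(sim_melt_curve(120), "scan range")
  # seeded noise is reproducible
  n1 <- sim_melt_curve(70, noise_sd = 50, seed = 7)
  n2 <- sim_melt_curve(70, noise_sd = 50, seed = 7)
  expect_identical(n1$signal, n2$signal)
})
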