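test_that("mass fraction from peak ratios honors the adjustment factor", {
  f <- signal_factors(0.89, 0.06)
  rec <- tibble::tibble(t0_uM = 50, p0_uM = 50,
                        high_norm = c(1, 0, 0.5),
                        low_norm = c(0, 0.89, 0.445))
  out <- mass_fraction_from_peaks(rec, f)
  expect_equal(out$theta, c(1, 0, 0.5))
  expect_equal(out$free_uM[2], 100)       # all monomer unassembled
  expect_equal(out$assembled_uM[3], 50)
  expect_error(mass_fraction_from_peaks(
    tibble::tibble(t0_uM = 50, p0_uM = 50, high_norm = 0, low_norm = 0), f))
})

test_that("Hill regression is exact on data generated from a Hill law", {
  L <- c(4, 6, 8, 12, 16, 20)
  th <- (L / 10)^3 / (1 + (L / 10)^3)
  h <- hill_analysis(tibble::tibble(theta = th, free_uM = L))
  expect_equal(h$hill_coefficient, 3, tolerance = 1e-12)
  expect_equal(h$apparent_kd_uM, 10, tolerance = 1e-10)
  expect_equal(h$r_squared, 1, tolerance = 1e-12)
  expect_equal(tidy(h)$estimate[1], 3, tolerance = 1e-12)
  # a single usable point is underdetermined
  expect_error(hill_analysis(tibble::tibble(theta = 0.5, free_uM = 10)),
               ">= 2 points")
  # saturated series carries no usable logit information
  expect_error(hill_analysis(tibble::tibble(theta = c(0.999, 0.9995),
                                            free_uM = c(5, 10))))
})

test_that("model-generated equimolar curves are cooperative (Hill slope above one)", {
  simp <- species_table("simplified")
  for (dg in c(1.5, 2.5, 3.6)) {
    # center the series on the pseudo-critical concentration for this energy
    lo <- -3; hi <- 12
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      mf <- solve_equilibrium(
        tibble::tibble(t0_uM = exp(mid), p0_uM = exp(mid)), dg, simp)$mass_fraction
      if (mf > 0.5) hi <- mid else lo <- mid
    }
    tots <- exp(seq((lo + hi) / 2 - 0.7, (lo + hi) / 2 + 0.7, length.out = 9))
    st <- solve_equilibrium(tibble::tibble(t0_uM = tots, p0_uM = tots), dg, simp)
    h <- hill_analysis(tibble::tibble(theta = st$mass_fraction,
                                      free_uM = st$low_mw_uM))
    expect_gt(h$hill_coefficient, 1)
  }
})

test_that("peak-derived mass fractions invert the signal model", {
  inc <- species_table("inclusive")
  f <- signal_factors(0.9, 0)
  st <- solve_equilibrium(tibble::tibble(t0_uM = c(25, 50, 75),
                                         p0_uM = c(25, 50, 75)), 3.6, inc)
  sg <- predict_normalized_signals(st, c(t = 2e4, p = 2e4), f)
  rec <- tibble::tibble(t0_uM = st$t0_uM, p0_uM = st$p0_uM,
                        high_norm = sg$high_signal, low_norm = sg$low_signal)
  out <- mass_fraction_from_peaks(rec, f)
  expect_equal(out$theta, st$mass_fraction, tolerance = 1e-9)
})

test_that("chevron summaries locate the equimolar minimum and propagate errors", {
  dat <- sim_cooperativity_dataset(3.6, noise_cv = 0, seed = 9)
  nm <- normalize_peak_areas(dat)
  ch <- chevron_summary(nm)
  vp <- ch[ch$series_id == "vary_p", ]
  vp <- vp[order(vp$variable_uM), ]
  # residual-component signal dips at the equimolar point
  expect_equal(vp$variable_uM[which.min(vp$low_mean)], 50)
  # assembled signal plateaus once pentamer is in excess: the per-uM slope
  # collapses relative to the limiting-component regime
  slope_below <- (vp$high_mean[vp$variable_uM == 50] -
                    vp$high_mean[vp$variable_uM == 12.5]) / (50 - 12.5)
  slope_above <- (vp$high_mean[vp$variable_uM == 150] -
                    vp$high_mean[vp$variable_uM == 50]) / (150 - 50)
  expect_lt(slope_above, 0.2 * slope_below)
  # error bars follow the ratio-propagation formula
  datn <- sim_cooperativity_dataset(3.6, noise_cv = 0.05, seed = 10)
  nmn <- normalize_peak_areas(datn)
  chn <- chevron_summary(nmn)
  one <- nmn[!nmn$is_reference & nmn$series_id == "vary_p" &
               nmn$p0_uM == 100, ]
  ref <- attr(nmn, "ref_high")
  expected_sd <- propagate_sd(mean(one$high_norm), stats::sd(one$high_norm),
                              1, ref[["sd"]] / ref[["mean"]])
  got <- chn[chn$series_id == "vary_p" & chn$variable_uM == 100, ]
  expect_equal(got$high_sd, expected_sd, tolerance = 1e-12)
})
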