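test_that("log-domain species concentrations match closed-form and high-precision evaluation", {
  inc <- species_table("inclusive")
  # unit Boltzmann factor: [T3P5] = 3 uM * 5 uM on the molar scale
  t3p5 <- inc[inc$species_id == "T3P5", ]
  expect_equal(log_species_concentration(t3p5, 3, 5, 0), log(1.5e-11),
               tolerance = 1e-12)
  # complete assembly at 5/5 uM free, dG = 3.6 (frozen 50-digit value)
  t60 <- inc[inc$species_id == "T60P60", ]
  expect_equal(log_species_concentration(t60, 5, 5, 3.6),
               frozen_log_conc_t60p60_5_5_36, tolerance = 1e-12)
  # T57P60 equals its printed closed form (moderate energy so the direct
  # double-precision product is representable)
  t57 <- inc[inc$species_id == "T57P60", ]
  ft <- 2.7; fp <- 11.3; dg <- 0.4
  direct <- 3^19 * 5^12 * (ft / 3e6)^19 * (fp / 5e6)^12 *
    exp(57 * dg / (1.98720e-3 * 296)) / 3
  expect_equal(log_species_concentration(t57, ft, fp, dg), log(direct),
               tolerance = 1e-12)
  # frozen 50-digit arbitrary-precision oracle over random states
  for (case in frozen_log_conc_oracle) {
    sp <- inc[inc$species_id == case[[1]], ]
    got <- log_species_concentration(sp, case[[2]], case[[3]], case[[4]])
    expect_lt(abs(got - case[[5]]), 1e-10)
  }
  expect_error(log_species_concentration(t60, -1, 5, 3.6))
})

test_that("totals_from_free does exact mass-balance bookkeeping", {
  simp <- species_table("simplified")
  zero <- totals_from_free(tibble::tibble(free_t_uM = 0, free_p_uM = 0), 3.6, simp)
  expect_equal(zero$t0_uM, 0)
  expect_equal(zero$p0_uM, 0)
  # simplified table: t0 = 60 [T60P60] 1e6 + free_t
  tf <- totals_from_free(tibble::tibble(free_t_uM = 5, free_p_uM = 5), 3.6, simp)
  conc <- exp(frozen_log_conc_t60p60_5_5_36)
  expect_equal(tf$t0_uM, 60 * conc * 1e6 + 5, tolerance = 1e-10)
  # ~1.4e-4 uM of monomer (both components pooled) sits in assemblies
  expect_equal(tf$t0_uM + tf$p0_uM - 10, 120 * conc * 1e6, tolerance = 1e-10)
  expect_equal(tf$t0_uM + tf$p0_uM - 10, 1.4e-4, tolerance = 0.01)
  # inclusive table: coefficient of each species is its monomer count
  inc <- species_table("inclusive")
  tfi <- totals_from_free(tibble::tibble(free_t_uM = 20, free_p_uM = 30), 2.0, inc)
  manual_t <- 20 + sum(inc$t_monomers * exp(purrr::map_dbl(
    seq_len(nrow(inc)), function(i) log_species_concentration(inc[i, ], 20, 30, 2.0)))) * 1e6
  expect_equal(tfi$t0_uM, manual_t, tolerance = 1e-12)
})

test_that("forward grid reproduces direct evaluation and spans the assembly transition", {
  simp <- species_table("simplified")
  one <- forward_grid(5, 5, 3.6, simp)
  direct <- totals_from_free(tibble::tibble(free_t_uM = 5, free_p_uM = 5), 3.6, simp)
  expect_equal(one$t0_uM, direct$t0_uM)
  expect_equal(one$conc_T60P60, exp(frozen_log_conc_t60p60_5_5_36),
               tolerance = 1e-12)

  g <- forward_grid(seq(0.5, 8, length.out = 10), seq(0.5, 8, length.out = 10),
                    3.6, simp)
  # totals strictly increase along each free axis
  by_t <- tidyr::pivot_wider(g[, c("free_t_uM", "free_p_uM", "t0_uM")],
                             names_from = "free_p_uM", values_from = "t0_uM")
  mat <- as.matrix(by_t[, -1])
  expect_true(all(apply(mat, 2L, function(col) all(diff(col) > 0))))
  # along the cross axis the assembled term can fall below double-precision
  # resolution of the free term, so ties (never decreases) are allowed
  expect_true(all(apply(mat, 1L, function(row) all(diff(row) >= 0))))
  # the equimolar diagonal crosses the pseudo-critical transition
  diag_g <- forward_grid(c(0.5, 10), c(0.5, 10), 3.6, simp)
  diag_g <- diag_g[diag_g$free_t_uM == diag_g$free_p_uM, ]
  expect_lt(min(diag_g$mass_fraction), 0.01)
  expect_gt(max(diag_g$mass_fraction), 0.8)
  expect_error(forward_grid(numeric(0), 1, 3.6, simp))
  expect_error(forward_grid(c(1, -2), 1, 3.6, simp))
})

test_that("the inverse solver reproduces the bisection oracle at equimolar input", {
  simp <- species_table("simplified")
  for (tot in c(50, 100)) {
    st <- solve_equilibrium(tibble::tibble(t0_uM = tot, p0_uM = tot), 3.6, simp)
    expect_equal(st$mass_fraction, oracle_equimolar_massfrac(tot, 3.6),
                 tolerance = 1e-8)
  }
  # the frozen oracle values themselves
  st100 <- solve_equilibrium(tibble::tibble(t0_uM = 100, p0_uM = 100), 3.6, simp)
  expect_equal(st100$mass_fraction, 0.922344967705163, tolerance = 1e-7)
  st50 <- solve_equilibrium(tibble::tibble(t0_uM = 50, p0_uM = 50), 3.6, simp)
  expect_equal(st50$mass_fraction, 0.848414209571689, tolerance = 1e-7)
})

test_that("solved states satisfy mass balance over random grids and energies", {
  inc <- species_table("inclusive")
  withr::with_seed(42, {
    tg <- tibble::tibble(t0_uM = runif(100, 0.5, 200),
                         p0_uM = runif(100, 0.5, 200))
  })
  for (dg in c(0, 3.6, 5, 10)) {
    st <- solve_equilibrium(tg, dg, inc)
    chk <- totals_from_free(st[, c("free_t_uM", "free_p_uM")], dg, inc)
    rel <- pmax(abs(chk$t0_uM - tg$t0_uM) / tg$t0_uM,
                abs(chk$p0_uM - tg$p0_uM) / tg$p0_uM)
    expect_lt(max(rel), 1e-9)
    expect_true(all(st$mass_fraction >= 0 & st$mass_fraction <= 1))
  }
  # no overflow/underflow at extreme energies and trace concentrations
  tiny <- solve_equilibrium(tibble::tibble(t0_uM = 1e-6, p0_uM = 1e-6), 10, inc)
  expect_true(is.finite(tiny$mass_fraction))
})

test_that("assembly is monotone in contact energy and total concentration", {
  simp <- species_table("simplified")
  mf_dg <- vapply(seq(2, 5, by = 0.5), function(dg) {
    solve_equilibrium(tibble::tibble(t0_uM = 50, p0_uM = 50), dg, simp)$mass_fraction
  }, numeric(1))
  expect_true(all(diff(mf_dg) >= 0))
  mf_tot <- solve_equilibrium(
    tibble::tibble(t0_uM = c(10, 25, 50, 100, 200), p0_uM = c(10, 25, 50, 100, 200)),
    3.6, simp)$mass_fraction
  expect_true(all(diff(mf_tot) >= 0))
})

test_that("intermediates are negligible at equimolar input for study-scale energies", {
  simp <- species_table("simplified")
  inc <- species_table("inclusive")
  for (dg in c(3.6, 4.1, 4.5)) for (tot in c(10, 50, 150)) {
    a <- solve_equilibrium(tibble::tibble(t0_uM = tot, p0_uM = tot), dg, simp)$mass_fraction
    b <- solve_equilibrium(tibble::tibble(t0_uM = tot, p0_uM = tot), dg, inc)$mass_fraction
    expect_lt(abs(a - b), 0.01)
  }
})

test_that("degenerate and zero-energy inputs behave physically", {
  inc <- species_table("inclusive")
  # one missing component: everything stays free
  st <- solve_equilibrium(tibble::tibble(t0_uM = 0, p0_uM = 50), 3.6, inc)
  expect_equal(st$free_p_uM, 50)
  expect_equal(st$mass_fraction, 0)
  expect_equal(st$high_mw_uM, 0)
  # no driving energy: assembly is immeasurable at bench concentrations
  st0 <- solve_equilibrium(tibble::tibble(t0_uM = 1000, p0_uM = 1000), 0, inc)
  expect_lt(st0$mass_fraction, 1e-6)
  expect_error(solve_equilibrium(tibble::tibble(t0_uM = -5, p0_uM = 5), 3.6, inc))
})

test_that("mass fraction bases agree for equal monomer masses and differ otherwise", {
  simp <- species_table("simplified")
  st <- solve_equilibrium(tibble::tibble(t0_uM = 60, p0_uM = 40), 4, simp)
  eqw <- default_components(trimer_mw = 14, pentamer_mw = 14)
  expect_equal(mass_fraction_assembled(st, "monomer"),
               mass_fraction_assembled(st, "mass", components = eqw))
  expect_equal(mass_fraction_assembled(st, "monomer"), st$mass_fraction)
  expect_error(mass_fraction_assembled(
    solve_equilibrium(tibble::tibble(t0_uM = 0, p0_uM = 0), 4, simp)))
})
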