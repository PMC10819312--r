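test_that("eob_activity matches its rate-based limit and scales as expected", {
  lam <- 1e-4 / 2  # lambda * t_real = 1e-4 with t_real = 2 h
  a <- eob_activity(counts = 1e4, lambda_h = lam, t_cool_h = 5, t_real_h = 2,
                    t_live_h = 1.96, efficiency = 0.003, intensity = 0.683)
  rate_form <- 1e4 * (2 / 1.96) /
    (3600 * 0.003 * 0.683 * 2 * exp(-lam * 5))
  expect_equal(a$activity_bq, rate_form, tolerance = 1e-3)

  base <- eob_activity(1e4, 0.01, 5, 2, 1.96, 0.003, 0.683)
  dbl_eff <- eob_activity(1e4, 0.01, 5, 2, 1.96, 0.006, 0.683)
  expect_equal(dbl_eff$activity_bq, base$activity_bq / 2)
  dbl_counts <- eob_activity(2e4, 0.01, 5, 2, 1.96, 0.003, 0.683)
  expect_equal(dbl_counts$activity_bq, base$activity_bq * 2)

  expect_error(eob_activity(1e4, 0.01, 5, 2, 1.7, 0.003, 0.683), "dead time")
  expect_error(eob_activity(1e4, 0.01, 5, 2, 2.5, 0.003, 0.683), "live time")
  expect_error(eob_activity(1e4, 0.01, 5, 2, 1.96, 0, 0.683), "positive")
})

test_that("monitor interpolation passes through the recommended values", {
  s1 <- monitor_sigma(26.3)
  expect_equal(s1$sigma_mb, 180.1)
  expect_equal(s1$unc_mb, 7.5)
  s2 <- monitor_sigma(67.9)
  expect_equal(s2$sigma_mb, 66.2)
  expect_equal(s2$unc_mb, 2.9)
  # shape preservation between neighbours
  tab <- monitor_cross_sections()
  for (i in seq_len(nrow(tab) - 1)) {
    mid <- (tab$energy_mev[i] + tab$energy_mev[i + 1]) / 2
    s <- monitor_sigma(mid)$sigma_mb
    expect_gte(s, min(tab$sigma_mb[i:(i + 1)]) - 1e-9)
    expect_lte(s, max(tab$sigma_mb[i:(i + 1)]) + 1e-9)
  }
  expect_error(monitor_sigma(20), "outside")
  expect_error(monitor_sigma(70), "outside")
})

test_that("recoil correction adds activities and reports the recoil fraction", {
  r <- add_recoil(99, 1)
  expect_equal(r$activity_bq, 100)
  expect_equal(r$recoil_fraction, 0.01)
  expect_equal(add_recoil(42, 0)$activity_bq, 42)
  # fraction invariant under common scaling
  expect_equal(add_recoil(990, 10)$recoil_fraction, 0.01)
  expect_error(add_recoil(-1, 0), "non-negative")
})

test_that("flux normalisation inverts the forward activation formula", {
  reg <- default_nuclides()
  lam57 <- lambda_per_hour(reg, "Ni-57")
  phi_true <- 6.24e11
  n_ni <- areal_atoms_cm2(22255, 58.6934)  # 25 um Ni
  sig <- monitor_sigma(30)
  a57 <- phi_true * n_ni * sig$sigma_mb * 1e-27 * saturation_factor(lam57, 1.5)
  got <- average_flux(a57, n_ni, sig$sigma_mb, lam57, 1.5)
  expect_equal(got$flux_pps, phi_true, tolerance = 1e-3)
  # doubling the monitor cross-section halves the flux
  half <- average_flux(a57, n_ni, 2 * sig$sigma_mb, lam57, 1.5)
  expect_equal(half$flux_pps, phi_true / 2, tolerance = 1e-9)
  # current/flux consistency: 100 nA = I/e protons per second
  expect_equal(protons_per_second(0.1), 6.2415e11, tolerance = 1e-4)
  expect_error(average_flux(a57, n_ni, sig$sigma_mb, lam57, 0), "positive")
})

test_that("production cross-section round-trips a noise-free synthetic foil", {
  reg <- default_nuclides()
  lam <- lambda_per_hour(reg, "Sc-47")
  phi <- 6.24e11; f <- 0.9932
  n_t <- areal_atoms_cm2(500, 47.9479)
  sigma_true <- 24.1  # mb at 29.3 MeV
  a <- phi * f * n_t * sigma_true * 1e-27 * saturation_factor(lam, 1.5)
  got <- production_cross_section(a, phi, 500, lam, 1.5, enrichment = f)
  expect_equal(got$sigma_mb, sigma_true, tolerance = 1e-3)
  # enrichment rescaling is an exact factor 1/f
  g1 <- production_cross_section(a, phi, 500, lam, 1.5, enrichment = 1)
  expect_equal(got$sigma_mb / g1$sigma_mb, 1 / f, tolerance = 1e-12)
  # reported uncertainty is never below the monitor (flux) contribution alone
  gu <- production_cross_section(a, phi, 500, lam, 1.5, enrichment = f,
                                 a_unc_bq = 0.03 * a, flux_rel_unc = 0.05)
  expect_gte(gu$unc_mb / gu$sigma_mb, 0.05)
})

test_that("uncertainty budget is a quadrature sum with sorted contributions", {
  expect_equal(uncertainty_budget(c(monitor = 0.05, other = 0))$total, 0.05)
  expect_equal(uncertainty_budget(c(a = 0.03, b = 0.04))$total, 0.05)
  b <- uncertainty_budget(c(monitor = 0.05, counting = 0.03,
                            areal = 0.05, eff = 0.02))
  expect_equal(b$total, 0.0794, tolerance = 1e-3)
  expect_equal(names(b$contributions)[1:2], c("monitor", "areal"))
  expect_error(uncertainty_budget(c(-0.01, 0.02)), "non-negative")
})

test_that("repeated counts combine by inverse-variance weighting", {
  cmb <- combine_activities(c(100, 110), c(5, 10))
  w <- 1 / c(5, 10)^2
  expect_equal(cmb$value, sum(w * c(100, 110)) / sum(w))
  expect_equal(cmb$unc, sqrt(1 / sum(w)))
  expect_lt(cmb$unc, 5)
})
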