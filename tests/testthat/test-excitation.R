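test_that("excitation fit anchors at threshold and interpolates shape-preservingly", {
  xs <- fit_excitation(c(20, 30), c(10, 20), threshold_mev = 10)
  expect_equal(predict(xs, 10), 0)
  s25 <- predict(xs, 25)
  expect_gt(s25, 10); expect_lt(s25, 20)
  expect_equal(predict(xs, c(20, 30)), c(10, 20))
  expect_equal(predict(xs, 5), 0)  # below threshold
  expect_warning(predict(xs, 35), "extrapolating")
  expect_equal(predict(xs, 35, warn_extrapolation = FALSE), 20)  # constant tail
  expect_error(fit_excitation(c(20, 20), c(1, 2), 10), "duplicate")
  expect_error(fit_excitation(c(20, 30), c(1, 2), 25), "threshold")
})

test_that("fits through the measured table are exact at the data points", {
  fits <- excitation_fits()
  expect_equal(predict(fits[["Sc-47"]], 29.3), 24.1)
  expect_equal(predict(fits[["Sc-44g"]], 26.7), 47.4)
  expect_equal(predict(fits[["Sc-46"]], 39.6), 63.7)
  # never negative anywhere on a dense grid
  for (p in names(fits)) {
    e <- seq(fits[[p]]$threshold_mev, fits[[p]]$e_max, length.out = 500)
    expect_true(all(predict(fits[[p]], e) >= 0), info = p)
  }
})

test_that("saturation factor has the right limits and Sc-47 80h/24h ratio", {
  expect_equal(saturation_factor(0.1, 0), 0)
  expect_equal(saturation_factor(5, 1e4), 1, tolerance = 1e-12)
  lam47 <- lambda_per_hour(default_nuclides(), "Sc-47")
  expect_equal(saturation_factor(lam47, 80) / saturation_factor(lam47, 24),
               2.665, tolerance = 5e-4)
})

test_that("thick-target integral is linear in current and zero for zero sigma", {
  reg <- default_nuclides()
  lam <- lambda_per_hour(reg, "Sc-47")
  zero <- fit_excitation(c(20, 30), c(0, 0), threshold_mev = 10)
  expect_equal(thick_target_eob_activity(zero, scenario(30, 24), lam), 0)
  xs <- excitation_fits()[["Sc-47"]]
  a1 <- thick_target_eob_activity(xs, scenario(30, 24, current_ua = 1), lam)
  a3 <- thick_target_eob_activity(xs, scenario(30, 24, current_ua = 3), lam)
  expect_equal(a3, 3 * a1, tolerance = 1e-12)
  # halving the integration step moves the result by < 0.1%
  a_half <- thick_target_eob_activity(xs, scenario(30, 24), lam, step_mev = 0.01)
  expect_lt(abs(a_half / a1 - 1), 1e-3)
})

test_that("yield table blanks products without measured support and reports mCi", {
  fits <- excitation_fits(products = c("Sc-47", "Sc-46", "Sc-44g",
                                       "Sc-44m", "Sc-43"))
  yt <- yield_table(fits, list(scenario(25, 24, name = "E<25"),
                               scenario(40, 24, name = "E<40")))
  e25 <- yt[yt$scenario == "E<25", ]
  expect_true(is.na(e25$activity_mbq[e25$nuclide == "Sc-46"]))
  expect_true(is.na(e25$activity_mbq[e25$nuclide == "Sc-43"]))
  expect_false(is.na(e25$activity_mbq[e25$nuclide == "Sc-47"]))
  e40 <- yt[yt$scenario == "E<40", ]
  expect_true(all(!is.na(e40$activity_mbq)))
  expect_equal(yt$activity_mci, yt$activity_mbq / 37)
})

test_that("80h/24h yield ratios equal saturation ratios for feeding-free products", {
  reg <- default_nuclides()
  fits <- excitation_fits(products = c("Sc-47", "Sc-44g", "Sc-44m"))
  for (nuc in names(fits)) {
    lam <- lambda_per_hour(reg, nuc)
    a24 <- thick_target_eob_activity(fits[[nuc]], scenario(30, 24), lam)
    a80 <- thick_target_eob_activity(fits[[nuc]], scenario(30, 80), lam)
    expect_equal(a80 / a24,
                 saturation_factor(lam, 80) / saturation_factor(lam, 24),
                 tolerance = 5e-3, info = nuc)
  }
})
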