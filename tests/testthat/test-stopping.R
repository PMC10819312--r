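test_that("stopping power agrees with an independent reference over 10-70 MeV", {
  ref <- utils::read.csv(test_path("stopping-reference.csv"))
  for (m in unique(ref$material)) {
    r <- ref[ref$material == m, ]
    got <- mass_stopping_power(r$energy_mev, m) * 1000  # MeV cm^2/g
    expect_true(all(abs(got / r$stopping_mev_cm2_g - 1) < 0.03),
                info = paste("material", m))
  }
})

test_that("stopping power decreases with energy and respects Bragg additivity", {
  for (m in c("Ti", "Al", "Ni", "kapton", "air"))
    expect_lt(mass_stopping_power(60, m), mass_stopping_power(20, m))
  # Bragg rule: explicit elemental sum equals the compound evaluation
  kap <- builtin_material("kapton")
  direct <- sum(vapply(names(kap$composition), function(el) {
    kap$composition[[el]] *
      mass_stopping_power(35, material(el, stats::setNames(1, el), 1))
  }, numeric(1)))
  expect_equal(mass_stopping_power(35, kap), direct, tolerance = 1e-12)
  expect_error(mass_stopping_power(0.5, "Al"), "validity floor")
})

test_that("degrade is exact on zero thickness and converges with step refinement", {
  b <- beam_state(30, 500)
  z <- foil_spec("Al", areal_density_ug_cm2 = 0)
  expect_identical(degrade(b, z)$exit$energy_mev, 30)

  f <- foil_spec("Al", thickness_um = 500)
  e1 <- degrade(b, f, n_min = 100)$exit$energy_mev
  e2 <- degrade(b, f, n_min = 200)$exit$energy_mev
  expect_lt(abs(e1 - e2) * 1000, 1)  # < 1 keV on halving the step

  # brute-force fine-step reference (0.1 um steps)
  e_ref <- degrade(b, f, n_min = 5000)$exit$energy_mev
  expect_lt(abs(e1 - e_ref) * 1000, 5)
  # ordering: exit < mid < entry
  d <- degrade(b, f)
  expect_lt(d$exit$energy_mev, d$mid$energy_mev)
  expect_lt(d$mid$energy_mev, 30)
})

test_that("degrade is deterministic and reports ranged-out foils", {
  b <- beam_state(30, 500)
  f <- foil_spec("Al", thickness_um = 700)
  expect_identical(degrade(b, f)$exit$energy_mev, degrade(b, f)$exit$energy_mev)
  thick <- foil_spec("Al", thickness_um = 10000, id = "block")
  expect_error(degrade(beam_state(20, 500), thick), "ranged-out")
  expect_error(degrade(beam_state(20, 500), thick), "block")
})

test_that("straggling is zero at zero thickness and grows with thickness", {
  f0 <- foil_spec("Al", areal_density_ug_cm2 = 0)
  expect_identical(straggling(f0, 30), 0)
  f1 <- foil_spec("Al", thickness_um = 250)
  f2 <- foil_spec("Al", thickness_um = 500)
  expect_gt(straggling(f2, 30), straggling(f1, 30))
})

test_that("stack propagation conserves energy bookkeeping", {
  stk <- read_stack(system.file("extdata", "example_stack.json",
                                package = "sc47yield"))
  prop <- propagate_stack(stk$beam, stk$layers)
  # strictly decreasing through the stack; mid strictly between entry and exit
  expect_true(all(prop$e_exit_mev < prop$e_entry_mev |
                    prop$areal_density_ug_cm2 == 0))
  expect_true(all(prop$e_mid_mev < prop$e_entry_mev))
  expect_true(all(prop$e_mid_mev > prop$e_exit_mev))
  expect_true(all(diff(prop$e_mid_mev) < 0))
  # total loss equals the sum of per-layer losses
  total <- prop$e_entry_mev[1] - prop$e_exit_mev[nrow(prop)]
  expect_equal(sum(prop$e_entry_mev - prop$e_exit_mev), total,
               tolerance = 1e-9)
  # single zero-thickness layer leaves the beam untouched
  p0 <- propagate_stack(beam_state(50, 500),
                        list(foil_spec("Al", areal_density_ug_cm2 = 0)))
  expect_equal(p0$e_exit_mev, 50)
  expect_error(propagate_stack(beam_state(50), list()), "non-empty")
})

test_that("a 70 to 18 MeV stack reproduces the measured energy ladder", {
  stk <- read_stack(system.file("extdata", "example_stack.json",
                                package = "sc47yield"))
  prop <- propagate_stack(stk$beam, stk$layers)
  tg <- prop[prop$role == "target", ]
  expect_equal(nrow(tg), 15)
  expect_equal(length(unique(round(tg$e_mid_mev, 2))), 15)
  expect_true(all(tg$e_mid_mev > 17.5 & tg$e_mid_mev < 68.5))
  expect_true(all(diff(tg$e_mid_mev) < 0))
  # combined energy uncertainty at the deepest foil stays below 900 keV
  expect_lte(max(prop$unc_mid_kev), 900)
  expect_true(all(prop$unc_mid_kev >= 500))
})
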