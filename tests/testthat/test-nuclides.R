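test_that("decay constants follow ln(2)/t1/2 with unit conversion to hours", {
  expect_equal(decay_constant(log(2), "h"), 1.0)
  # hand calculations: ln2/(3.3492*24) and ln2/4.0420
  expect_equal(decay_constant(3.3492, "d"), 0.0086233, tolerance = 1e-4)
  expect_equal(decay_constant(4.0420, "h"), 0.171486, tolerance = 1e-5)
  expect_equal(decay_constant(3600, "s"), decay_constant(1, "h"))
  expect_error(decay_constant(0), "positive")
  expect_error(decay_constant(-2, "d"), "positive")
})

test_that("decay constant is strictly decreasing in half-life", {
  hl <- sort(runif(25, 0.1, 1000))
  lam <- decay_constant(hl, "h")
  expect_true(all(diff(lam) < 0))
})

test_that("registry half-lives and decay constants are mutually consistent", {
  reg <- default_nuclides()
  expect_equal(nrow(reg$nuclides), 7)
  for (n in reg$nuclides$nuclide) {
    t12 <- half_life_hours(reg, n)
    lam <- lambda_per_hour(reg, n)
    expect_equal(exp(-lam * t12), 0.5, tolerance = 1e-12)
  }
})

test_that("quantification-line selection drops interference-flagged lines", {
  reg <- default_nuclides()
  sc46 <- quantification_lines(reg, "Sc-46")
  expect_equal(nrow(sc46), 1)
  expect_equal(sc46$gamma_energy_kev, 889.277)
  expect_equal(sc46$gamma_intensity, 0.999840)
  ni57 <- quantification_lines(reg, "Ni-57")
  expect_equal(ni57$gamma_energy_kev, 1377.63)
  expect_equal(ni57$gamma_intensity, 0.817)
  sc47 <- quantification_lines(reg, "Sc-47")
  expect_equal(sc47$gamma_energy_kev, 159.381)
  expect_equal(sc47$gamma_intensity, 0.683)
  # the shared 1157 keV line of Sc-44m is not usable for quantification
  sc44m <- quantification_lines(reg, "Sc-44m")
  expect_equal(sc44m$gamma_energy_kev, 271.251)
  expect_error(quantification_lines(reg, "Xx-99"), "unknown nuclide")
})

test_that("nuclide table loader validates its schema and round-trips", {
  reg <- default_nuclides()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_nuclide_table(reg, tmp)
  reg2 <- load_nuclide_table(tmp)
  expect_equal(reg2$nuclides, reg$nuclides)
  expect_equal(reg2$lines[order(reg2$lines$nuclide, reg2$lines$gamma_energy_kev), ],
               reg$lines[order(reg$lines$nuclide, reg$lines$gamma_energy_kev), ],
               ignore_attr = TRUE)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("nuclide,half_life_value", empty)
  expect_error(load_nuclide_table(empty), "missing mandatory field")

  bad <- withr::local_tempfile(fileext = ".csv")
  df <- utils::read.csv(system.file("extdata", "nuclide_table.csv",
                                    package = "sc47yield"))
  df$half_life_value[1] <- 0
  utils::write.csv(df, bad, row.names = FALSE)
  expect_error(load_nuclide_table(bad), "half-life must be positive")
})

test_that("reaction thresholds are physically ordered", {
  thr <- reaction_thresholds()
  expect_true(all(thr > 0))
  expect_lt(thr[["V-48"]], thr[["Sc-47"]])      # (p,n) is the cheapest channel
  expect_lt(thr[["Sc-47"]], thr[["Sc-46"]])     # more nucleons out, higher threshold
  expect_equal(thr[["Sc-44m"]] - thr[["Sc-44g"]], 0.27124 * (47.9479 + 1.00728) / 47.9479,
               tolerance = 1e-6)
  expect_equal(thr[["Sc-47"]], 11.69, tolerance = 0.01)
})
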