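test_that("decay is the identity at dt = 0 and pure exponential without feeding", {
  a0 <- activity_set(c("Sc-47" = 100, "Sc-46" = 5, "Sc-44g" = 300))
  expect_equal(decay_activities(a0, 0)$activities, a0$activities)
  # no Sc-44m present: Sc-44g decays purely exponentially
  reg <- default_nuclides()
  lg <- lambda_per_hour(reg, "Sc-44g")
  a24 <- decay_activities(a0, 24)
  expect_equal(a24$activities[["Sc-44g"]], 300 * exp(-lg * 24), tolerance = 1e-12)
  expect_error(decay_activities(a0, -1), "non-negative")
  expect_error(activity_set(c("Sc-47" = -1)), "non-negative")
})

test_that("Bateman solution matches a fine-step ODE integration", {
  skip_if_not_installed("deSolve")
  reg <- default_nuclides()
  lm <- lambda_per_hour(reg, "Sc-44m")
  lg <- lambda_per_hour(reg, "Sc-44g")
  b <- it_branching_sc44()
  a0 <- activity_set(c("Sc-44m" = 154, "Sc-44g" = 1792, "Sc-47" = 198))
  # ODE in atom numbers N = A/lambda; feed term b*lm*Nm into the ground state
  n0 <- c(Nm = 154 / lm, Ng = 1792 / lg)
  rhs <- function(t, y, p) list(c(-lm * y[1], b * lm * y[1] - lg * y[2]))
  times <- c(0, 10, 50, 120, 400)
  sol <- deSolve::ode(n0, times, rhs, NULL, method = "lsoda",
                      rtol = 1e-11, atol = 1e-12)
  for (i in seq_along(times)) {
    got <- decay_activities(a0, times[i])$activities
    expect_equal(got[["Sc-44m"]], unname(lm * sol[i, "Nm"]), tolerance = 1e-8)
    expect_equal(got[["Sc-44g"]], unname(lg * sol[i, "Ng"]), tolerance = 1e-8)
  }
})

test_that("Bateman feeding conserves nuclei", {
  # integral of lambda_g * N_g over all time equals the initial ground-state
  # nuclei plus the branched share of the isomer nuclei
  reg <- default_nuclides()
  lm <- lambda_per_hour(reg, "Sc-44m")
  lg <- lambda_per_hour(reg, "Sc-44g")
  b <- it_branching_sc44()
  a0 <- activity_set(c("Sc-44m" = 50, "Sc-44g" = 200))
  ag <- function(t) vapply(t, function(ti)
    decay_activities(a0, ti)$activities[["Sc-44g"]], numeric(1))
  decays_g <- stats::integrate(ag, 0, Inf, rel.tol = 1e-10)$value
  expected <- 200 / lg + b * 50 / lm
  expect_equal(decays_g, expected, tolerance = 1e-6)
})

test_that("radionuclidic purity is an activity fraction over Sc isotopes only", {
  expect_equal(rnp(activity_set(c("Sc-47" = 10))), 1)
  expect_equal(rnp(activity_set(c("Sc-47" = 5, "Sc-46" = 5))), 0.5)
  # V-48 is excluded from the denominator
  expect_equal(rnp(activity_set(c("Sc-47" = 5, "Sc-46" = 5, "V-48" = 90))), 0.5)
  expect_error(rnp(activity_set(c("Sc-47" = 0, "Sc-46" = 0))), "undefined")
  a0 <- reference_activity_set(40, 24)
  r <- rnp_curve(a0, seq(0, 3000, by = 25))$rnp
  expect_true(all(r >= 0 & r <= 1))
})

test_that("purity grows monotonically when no impurity outlives Sc-47", {
  a0 <- reference_activity_set(30, 24)  # no Sc-46, no Sc-43
  r <- rnp_curve(a0, seq(0, 4000, by = 10))$rnp
  expect_true(all(diff(r) > 0))
  m <- max_rnp(a0, horizon_h = 2000)
  expect_true(m$monotone)
  expect_equal(m$t_h, 2000)
})

test_that("time_to_rnp finds the crossing and detects unreachable targets", {
  a0 <- activity_set(c("Sc-47" = 10, "Sc-46" = 1e-4))
  expect_equal(time_to_rnp(a0, 0.99), 0)
  # with substantial long-lived Sc-46 the 99% target is never reached
  e40 <- reference_activity_set(40, 24)
  expect_identical(time_to_rnp(e40, 0.99), Inf)
  # crossing consistency: purity at the returned time equals the target
  e30 <- reference_activity_set(30, 24)
  t99 <- time_to_rnp(e30, 0.99)
  expect_equal(rnp(decay_activities(e30, t99)), 0.99, tolerance = 1e-4)
  expect_error(time_to_rnp(e30, 1.2), "target purity")
})
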