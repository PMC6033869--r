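test_that("step profile is the on/off envelope", {
  p <- make_step_profile(2, 1, 1)
  expect_equal(profile_voltage(p, c(0, 0.5, 0.999)), c(2, 2, 2))
  expect_equal(profile_voltage(p, c(1.0, 1.5, 2.0)), c(0, 0, 0))
  expect_equal(p$duration, 2)

  z <- make_step_profile(0, 1, 1)
  expect_equal(profile_voltage(z, seq(0, 2, 0.25)), rep(0, 9))
  expect_error(make_step_profile(-1, 1, 1), ">= 0")
  expect_error(make_step_profile(1, 0, 1), "> 0")
})

test_that("stepwise profile is a symmetric staircase", {
  p <- make_stepwise_profile(c(0.5, 1, 2), 1)
  expect_equal(length(p$segments), 7)
  expect_equal(p$duration, 7)
  mids <- seq(0.5, 6.5, by = 1)
  expect_equal(profile_voltage(p, mids), c(0, 0.5, 1, 2, 1, 0.5, 0))
  # time-reversal symmetry about the midpoint
  tq <- seq(0.1, 6.9, by = 0.2)
  expect_equal(profile_voltage(p, tq), rev(profile_voltage(p, 7 - tq)))

  # single level reduces to a step with zero pads
  s <- make_stepwise_profile(1.5, 0.25)
  expect_equal(profile_voltage(s, c(0.1, 0.35, 0.6)), c(0, 1.5, 0))
  expect_error(make_stepwise_profile(numeric(0), 1), "non-empty")
})

test_that("triangular profile matches the reference ramp", {
  p <- make_triangular_profile(2, 20)
  # V = 0.2 t on the rise, 4 - 0.2 t on the fall
  expect_equal(profile_voltage(p, c(5, 10, 15)), c(1, 2, 1))
  expect_equal(profile_voltage(p, c(0, 20)), c(0, 0))
  p25 <- make_triangular_profile(2.5, 20)
  expect_equal(profile_voltage(p25, 10), 2.5)
})

test_that("sinusoidal profile is the half-sine envelope", {
  p <- make_sinusoidal_profile(2, 5)
  expect_equal(profile_voltage(p, 2.5), 2)
  expect_equal(profile_voltage(p, c(0, 5)), c(0, 0))
  expect_equal(profile_voltage(p, 1.25), 2 * sin(pi / 4))
  p1 <- make_sinusoidal_profile(1, 5)
  expect_equal(max(profile_voltage(p1, seq(0, 5, 0.01))), 1,
               tolerance = 1e-3)
})

test_that("profiles are non-negative with additive durations", {
  profiles <- list(make_step_profile(2, 1, 1),
                   make_stepwise_profile(c(0.5, 1, 2), 0.25),
                   make_triangular_profile(2.5, 20),
                   make_sinusoidal_profile(2, 5),
                   make_custom_profile(c(0, 1, 3), c(0, 2, 0)))
  for (p in profiles) {
    tq <- seq(0, p$duration, length.out = 301)
    expect_true(all(profile_voltage(p, tq) >= 0))
    segs <- p$segments
    durs <- vapply(segs, function(s) s$t1 - s$t0, numeric(1))
    expect_equal(sum(durs), p$duration)
  }
})

test_that("stress law reproduces the fitted values with a zero closure", {
  law <- stress_law()
  expect_identical(stress_from_voltage(law, 0), 0)
  # direct polynomial evaluations on the fitted domain
  expect_equal(stress_from_voltage(law, 1) * 1e6, 3.65 - 2.63 + 0.71)
  expect_equal(stress_from_voltage(law, 2) * 1e6, 14.6 - 5.26 + 0.71)
  # continuity at the closure boundary
  eps <- 1e-9
  expect_equal(stress_from_voltage(law, 0.5 - eps),
               stress_from_voltage(law, 0.5 + eps), tolerance = 1e-6)
  # nondecreasing on the operating range
  v <- seq(0, 3, by = 0.01)
  expect_true(all(diff(stress_from_voltage(law, v)) >= 0))
  expect_error(stress_from_voltage(law, -0.1), ">= 0")

  raw <- stress_law(closure = "raw_poly")
  expect_equal(stress_from_voltage(raw, 0) * 1e6, 0.71)
})
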