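test_that("shear modulus follows the piecewise law, left-closed", {
  mat <- default_material()
  expect_equal(shear_modulus(mat, 1.2), 3.02e-6)
  expect_equal(shear_modulus(mat, 1.4), 3.02e-6)   # boundary convention
  expect_equal(shear_modulus(mat, 2.1),
               0.21e-6 * exp(2.06 * 2.1) - 0.25e-6)
  expect_equal(shear_modulus(mat, 2.1) * 1e6, 15.65, tolerance = 1e-3)
  expect_error(shear_modulus(mat, 0.9), ">= 1")

  # blend variant is continuous across the break: no step anywhere near the
  # size of the fitted branch gap (~0.5 uN/m)
  bl <- material_model(mu_continuity = "blend")
  lam <- seq(1.3, 1.5, by = 0.001)
  mus <- shear_modulus(bl, lam)
  expect_true(all(abs(diff(mus)) < 2e-8))
  # discontinuous variant jumps at the break
  pr <- shear_modulus(default_material(), c(1.4, 1.400001))
  expect_gt(diff(pr), 4e-7)
})

test_that("viscosity is t_c times the modulus and matches the reported viscosity law", {
  mat <- default_material()
  expect_equal(viscosity(mat, 1.2) * 1e6, 0.14 * 3.02)
  expect_equal(round(viscosity(mat, 1.2) * 1e6, 2), 0.42)
  # reported large-deformation viscosity law 0.03 exp(2.06 lam) - 0.035 is
  # the product t_c * mu(lam) with coefficients rounded to two digits
  # (0.14 x 0.21 = 0.0294, 0.14 x 0.25 = 0.035), hence the ~2% slack
  expect_equal(viscosity(mat, 2.0) * 1e6,
               0.03 * exp(2.06 * 2.0) - 0.035, tolerance = 0.03)
  none <- material_model(t_c = 0)
  expect_identical(viscosity(none, 1.2), 0)
})

test_that("shear strain is the quadratic-invariant form", {
  expect_identical(shear_strain(1), 0)
  expect_equal(shear_strain(2), 1.875)
  lam <- seq(0.5, 3, by = 0.01)
  expect_true(all(diff(shear_strain(lam)) > 0))
  expect_error(shear_strain(0), "> 0")
})

test_that("stress from force averages half the force over the minor axis", {
  expect_identical(shear_stress_from_force(0, 2.6e-6), 0)
  expect_equal(shear_stress_from_force(2.08e-11, 2.6e-6), 2.0e-6)
  expect_equal(shear_stress_from_force(1e-11, 1.3e-6),
               2 * shear_stress_from_force(1e-11, 2.6e-6))
  expect_error(shear_stress_from_force(1e-11, 0), "> 0")
})

test_that("rest is a fixed point and constant stress reaches equilibrium", {
  mat <- default_material()
  quiet <- simulate_deformation(mat, function(t) 0, t_span = 2)
  expect_true(all(abs(quiet$lambda - 1) < 1e-8))

  # constant stress: end state matches an independent bisection oracle
  for (s_u in c(0.5, 1.73, 5)) {
    sim <- simulate_deformation(mat, function(t) s_u * 1e-6,
                                t_span = 20 * mat$t_c)
    lam_oracle <- bisect_equilibrium(s_u * 1e-6, 3.02e-6)
    if (lam_oracle > 1.4) {
      lam_oracle <- equilibrium_lambda(mat, s_u * 1e-6)
    }
    expect_lt(abs(tail(sim$lambda, 1) - lam_oracle), 1e-4)
  }
})

test_that("recovery after release decays like exp(-t/t_c) when linear", {
  mat <- default_material()
  sim <- simulate_deformation(mat, function(t) 0, lam0 = 1.05,
                              t_span = 1, output_dt = 0.001)
  # log-slope of the (lambda - 1) tail approximates -1/t_c near lambda = 1
  d <- sim$lambda - 1
  use <- sim$time > 0.3 & d > 1e-8
  slope <- coef(lm(log(d[use]) ~ sim$time[use]))[2]
  expect_equal(unname(-1 / slope), mat$t_c, tolerance = 0.02)

  # full recovery is monotone with no plastic offset
  sim2 <- simulate_deformation(mat, function(t) 0, lam0 = 1.3, t_span = 2)
  expect_true(all(diff(sim2$lambda) <= 1e-12))
  expect_lt(abs(tail(sim2$lambda, 1) - 1), 1e-4)
})

test_that("equilibrium_lambda agrees with bisection and is monotone", {
  mat <- default_material()
  expect_identical(equilibrium_lambda(mat, 0), 1)
  expect_equal(equilibrium_lambda(mat, 1.73e-6),
               bisect_equilibrium(1.73e-6, 3.02e-6), tolerance = 1e-8)
  sigmas <- seq(0, 15e-6, length.out = 40)
  lams <- vapply(sigmas, function(s) equilibrium_lambda(mat, s), numeric(1))
  expect_true(all(diff(lams) >= 0))
  # stresses inside the modulus-jump gap pin the equilibrium at the break
  gap_lo <- 2 * 3.02e-6 * (1.4^2 - 1.4^-2) / 4
  gap_hi <- 2 * (0.21e-6 * exp(2.06 * 1.4) - 0.25e-6) * (1.4^2 - 1.4^-2) / 4
  expect_equal(equilibrium_lambda(mat, (gap_lo + gap_hi) / 2), 1.4)
  expect_error(equilibrium_lambda(mat, 1), "equilibrium")
})

test_that("t_c = 0 gives the quasi-static elastic response", {
  el <- material_model(t_c = 0)
  sim <- simulate_cell(el, make_triangular_profile(1, 2),
                       output_dt = 0.01)
  lam_expect <- vapply(stress_from_voltage(default_law(),
                                           profile_voltage(
                                             make_triangular_profile(1, 2),
                                             sim$time)),
                       function(s) equilibrium_lambda(el, s), numeric(1))
  expect_equal(sim$lambda, lam_expect, tolerance = 1e-9)
})

test_that("recovery-time fit roundtrips the defining relation", {
  t <- seq(0, 2, by = 0.01)
  sr <- sr_trace_from_tc(t, t_c = 0.20, sr0 = 1.8, sr_inf = 1.0)
  track <- cell_track(t, a = sr * 2.6e-6, b = rep(2.6e-6, length(t)))
  expect_equal(fit_recovery_tc(track, 0), 0.20, tolerance = 1e-3)

  # other true values roundtrip too
  for (tc in c(0.1, 0.14, 0.3)) {
    sr <- sr_trace_from_tc(t, tc, 1.5, 1.0)
    track <- cell_track(t, a = sr * 2.6e-6, b = rep(2.6e-6, length(t)))
    expect_equal(fit_recovery_tc(track, 0), tc, tolerance = tc * 1e-3)
  }
})

test_that("recovery-time fit tolerates frame noise", {
  t <- seq(0, 0.99, by = 0.01)                      # 100 frames at 100 fps
  sr_clean <- sr_trace_from_tc(t, 0.20, 1.8, 1.0)
  set.seed(7)
  errs <- replicate(20, {
    sr <- sr_clean + rnorm(length(t), 0, 0.01)
    track <- cell_track(t, a = sr * 2.6e-6, b = rep(2.6e-6, length(t)))
    fit_recovery_tc(track, 0) / 0.20 - 1
  })
  expect_lt(median(abs(errs)), 0.10)
})

test_that("degenerate recovery traces raise a fit error", {
  t <- seq(0, 1, by = 0.01)
  flat <- cell_track(t, a = rep(3.0e-6, length(t)),
                     b = rep(2.6e-6, length(t)))
  expect_error(fit_recovery_tc(flat, 0), "decay")
})

test_that("cell_track validates inputs and derives lambda and SR", {
  t <- c(0, 0.01, 0.02)
  tr <- cell_track(t, a = c(4, 4.2, 4.4) * 1e-6, b = c(2.6, 2.5, 2.4) * 1e-6)
  expect_equal(tr$lambda, 2.6 / c(2.6, 2.5, 2.4))
  expect_equal(tr$sr, c(4 / 2.6, 4.2 / 2.5, 4.4 / 2.4))
  expect_error(cell_track(c(0, 0, 1), c(1, 1, 1), c(1, 1, 1)),
               "increasing")
  expect_error(cell_track(t, c(1, -1, 1) * 1e-6, c(1, 1, 1) * 1e-6), "> 0")
})
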