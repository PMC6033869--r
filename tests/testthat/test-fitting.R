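test_that("stress-law fit roundtrips exact quadratic data", {
  v <- seq(0.5, 3, by = 0.5)
  s <- (3.65 * v^2 - 2.63 * v + 0.71) * 1e-6
  law <- fit_stress_voltage(v, s)
  expect_equal(law$p2, 3.65, tolerance = 1e-10)
  expect_equal(law$p1, -2.63, tolerance = 1e-10)
  expect_equal(law$p0, 0.71, tolerance = 1e-10)
  expect_error(fit_stress_voltage(c(1, 2), c(1, 2) * 1e-6), "3 distinct")
})

test_that("stress-law fit is stable under replicate noise", {
  v <- rep(seq(0.5, 3, by = 0.5), each = 14)
  set.seed(11)
  s <- (3.65 * v^2 - 2.63 * v + 0.71 + rnorm(length(v), 0, 0.1)) * 1e-6
  law <- fit_stress_voltage(v, s)
  expect_equal(law$p2, 3.65, tolerance = 0.1)
  expect_equal(law$p1, -2.63, tolerance = 0.1)
})

test_that("modulus-law fit roundtrips the piecewise exponential", {
  lam <- c(seq(1.05, 1.4, by = 0.05), seq(1.45, 2.1, by = 0.05))
  mu <- ifelse(lam <= 1.4, 3.02e-6, 0.21e-6 * exp(2.06 * lam) - 0.25e-6)
  fit <- fit_mu_lambda(lam, mu)
  expect_equal(fit$mu_small, 3.02e-6, tolerance = 1e-9)
  expect_equal(fit$mu_exp_amp, 0.21e-6, tolerance = 1e-6 * 0.21e-6)
  expect_equal(fit$mu_exp_rate, 2.06, tolerance = 1e-6)
  expect_equal(fit$mu_exp_offset, 0.25e-6, tolerance = 1e-5 * 0.25e-6)
  # recovered law stays below the observed ceiling at lambda = 2.1
  mu21 <- fit$mu_exp_amp * exp(fit$mu_exp_rate * 2.1) - fit$mu_exp_offset
  expect_lte(mu21 * 1e6, 16.7)
  expect_error(fit_mu_lambda(c(1.1, 1.2), c(3e-6, 3e-6)), "both sides")
})

test_that("modulus-law fit tolerates multiplicative noise", {
  # the offset exponential is weakly identified on a single noisy draw, so
  # the tolerance is checked on the Monte-Carlo median over fixed seeds
  lam <- c(seq(1.05, 1.4, by = 0.025), seq(1.45, 2.1, by = 0.025))
  mu0 <- ifelse(lam <= 1.4, 3.02e-6, 0.21e-6 * exp(2.06 * lam) - 0.25e-6)
  errs <- vapply(1:10, function(seed) {
    set.seed(seed)
    mu <- mu0 * (1 + rnorm(length(mu0), 0, 0.05))
    fit <- fit_mu_lambda(lam, mu)
    c(rate = abs(fit$mu_exp_rate / 2.06 - 1),
      small = abs(fit$mu_small / 3.02e-6 - 1))
  }, numeric(2))
  expect_lt(median(errs["rate", ]), 0.15)
  expect_lt(median(errs["small", ]), 0.05)
})

test_that("plateau inversion is the inverse of the equilibrium", {
  expect_equal(extract_mu_from_plateau(1.73e-6, 1.3135) * 1e6, 3.02,
               tolerance = 1e-3)
  mat <- default_material()
  for (mu_u in c(2, 3.02, 5)) {
    m <- material_model(mu_small = mu_u * 1e-6, lambda_break = 10)
    lam <- equilibrium_lambda(m, 2e-6)
    expect_equal(extract_mu_from_plateau(2e-6, lam), mu_u * 1e-6,
                 tolerance = 1e-8)
  }
  expect_error(extract_mu_from_plateau(0, 1.3), "> 0")
  expect_error(extract_mu_from_plateau(1e-6, 1), "> 1")
})

test_that("material recovery roundtrips noiseless tracks", {
  set <- make_track_set(6, voltages = c(0.5, 1, 2), axis_sd = 0)
  fit <- recover_material(set$tracks, set$profiles)
  expect_s3_class(fit, "material_fit")
  expect_equal(fit$material$mu_small, 3.02e-6, tolerance = 0.01)
  expect_equal(fit$material$t_c, 0.14, tolerance = 0.01)
  expect_error(recover_material(list(), list()), "non-empty")
})

test_that("material recovery refits the exponential branch when data allow", {
  # voltages whose plateaus fall above the break at distinct ratios
  set <- make_track_set(8, voltages = c(1, 1.8, 2.2, 2.6), axis_sd = 0,
                        on = 2)
  fit <- recover_material(set$tracks, set$profiles)
  expect_true(fit$exp_branch_fitted)
  expect_equal(fit$material$mu_exp_rate, 2.06, tolerance = 0.05 * 2.06)
})

test_that("material recovery is permutation invariant and noise tolerant", {
  set <- make_track_set(20, voltages = c(0.5, 1, 2), axis_sd = 3.9e-8,
                        seed = 100)
  fit <- recover_material(set$tracks, set$profiles)
  expect_lt(abs(fit$material$mu_small / 3.02e-6 - 1), 0.05)
  expect_lt(abs(fit$material$t_c / 0.14 - 1), 0.10)

  perm <- sample(seq_along(set$tracks))
  fit2 <- recover_material(set$tracks[perm], set$profiles[perm])
  expect_equal(fit2$material$mu_small, fit$material$mu_small,
               tolerance = 1e-12)
  expect_equal(fit2$material$t_c, fit$material$t_c, tolerance = 1e-12)
})

test_that("material_fit methods expose the fitted model", {
  set <- make_track_set(4, voltages = c(0.5, 1, 2), axis_sd = 0)
  fit <- recover_material(set$tracks, set$profiles)
  cf <- coef(fit)
  expect_named(cf, c("mu_small", "mu_exp_amp", "mu_exp_rate",
                     "mu_exp_offset", "lambda_break", "t_c"))
  expect_output(print(fit), "material_fit")
  expect_output(print(summary(fit)), "holds equilibrated")

  pred <- predict(fit, make_step_profile(1, 1, 1))
  expect_s3_class(pred, "kv_simulation")
  expect_gt(max(pred$lambda), 1.2)

  res <- residuals(fit)
  expect_length(res, nrow(fit$samples))
  expect_true(all(abs(res) < 1e-2))

  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "cell_track")
})

test_that("plateau detection flags unequilibrated holds", {
  mat <- default_material()
  law <- default_law()
  long <- simulate_cell(mat, make_stepwise_profile(c(0.5, 1, 2), 1), law)
  short <- simulate_cell(mat, make_stepwise_profile(c(0.5, 1, 2), 0.25), law)
  ps_long <- plateau_summary(long$time, long$lambda,
                             make_stepwise_profile(c(0.5, 1, 2), 1))
  ps_short <- plateau_summary(short$time, short$lambda,
                              make_stepwise_profile(c(0.5, 1, 2), 0.25))
  expect_true(all(ps_long$equilibrated))
  expect_false(any(ps_short$equilibrated))
})
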