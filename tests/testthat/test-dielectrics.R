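test_that("complex permittivity follows the lossy-dielectric convention", {
  # lossless media have no imaginary part
  expect_equal(complex_permittivity(dielectric_spec(59, 0), 1e6), 59 + 0i)
  expect_equal(complex_permittivity(dielectric_spec(4.44, 0), 1.58e6),
               4.44 + 0i)
  # conducting medium: eps - j sigma / (omega eps0), negative imaginary part
  em <- complex_permittivity(dielectric_spec(78, 0.018), 1.58e6)
  expect_equal(Re(em), 78)
  expect_equal(Im(em), -0.018 / (2 * pi * 1.58e6 * 8.8541878128e-12),
               tolerance = 1e-12)
  expect_lt(Im(em), -204)
  expect_gt(Im(em), -206)
  expect_error(complex_permittivity(dielectric_spec(78, 0.018), 0),
               "positive")
  expect_error(dielectric_spec(-1, 0), "rel_permittivity")
})

test_that("depolarization factors obey sphere, sum and prolate oracles", {
  sphere <- depolarization_factors(ellipsoid_geometry(1e-6, 1e-6, 1e-6))
  expect_equal(unname(sphere), rep(1 / 3, 3), tolerance = 1e-9)

  # sum rule across assorted triaxial shapes
  shapes <- list(c(4.2, 2.6, 1.3), c(2, 1, 1), c(1, 2, 3), c(5, 0.7, 0.1),
                 c(3.9, 3.9, 1.3))
  for (s in shapes) {
    A <- depolarization_factors(ellipsoid_geometry(s[1] * 1e-6, s[2] * 1e-6,
                                                   s[3] * 1e-6))
    expect_equal(sum(A), 1, tolerance = 1e-9)
    expect_true(all(A > 0 & A < 1))
  }

  # prolate spheroid closed form as independent oracle
  for (ratio in c(1.5, 2, 4)) {
    A <- depolarization_factors(ellipsoid_geometry(ratio * 1e-6, 1e-6, 1e-6))
    expect_equal(unname(A[1]), prolate_A_a(ratio, 1), tolerance = 1e-8)
    expect_equal(unname(A[2]), unname(A[3]), tolerance = 1e-9)
  }

  expect_error(ellipsoid_geometry(0, 1e-6, 1e-6), "semi-axes")
})

test_that("stretching the a axis strictly decreases its factor", {
  ratios <- c(1, 1.2, 1.5, 2, 3)
  As <- vapply(ratios, function(r) {
    depolarization_factors(ellipsoid_geometry(r * 2.6e-6, 2.6e-6, 1.3e-6))[1]
  }, numeric(1))
  expect_true(all(diff(As) < 0))
})

test_that("shell CM factor collapses to the homogeneous oracle", {
  geom <- ellipsoid_geometry(4.2e-6, 2.6e-6, 1.3e-6)
  ctx <- excitation_context(1.58e6, dielectric_spec(78, 0.018))
  A1 <- depolarization_factors(geom)[[1]]

  # identical shell and core: exact collapse whatever the thickness
  same <- cell_dielectrics(dielectric_spec(59, 0.31),
                           dielectric_spec(59, 0.31), 4.5e-9)
  f <- cm_factor(geom, same, ctx, "a")
  ep <- complex_permittivity(dielectric_spec(59, 0.31), 1.58e6)
  em <- complex_permittivity(dielectric_spec(78, 0.018), 1.58e6)
  expect_equal(f, homogeneous_cm(ep, em, A1), tolerance = 1e-10)

  # vanishing shell: approaches homogeneous cytoplasm
  thin <- cell_dielectrics(dielectric_spec(4.44, 10),
                           dielectric_spec(59, 0.31), 1e-14)
  f_thin <- cm_factor(geom, thin, ctx, "a")
  expect_lt(Mod(f_thin - homogeneous_cm(ep, em, A1)) /
              Mod(homogeneous_cm(ep, em, A1)), 1e-6)
})

test_that("homogeneous lossless sphere reproduces the classical factor", {
  sphere <- ellipsoid_geometry(2e-6, 2e-6, 2e-6)
  ctx <- excitation_context(1e6, dielectric_spec(2, 0))
  cell <- cell_dielectrics(dielectric_spec(4, 0), dielectric_spec(4, 0),
                           1e-12)
  f <- cm_factor(sphere, cell, ctx, "a")
  # (eps_p - eps_m)/(eps_p + 2 eps_m) = 1/4 for eps_p = 2 eps_m
  expect_equal(Re(f), 0.25, tolerance = 1e-9)
  expect_equal(Im(f), 0, tolerance = 1e-12)

  # boundedness of the homogeneous lossless sphere factor
  for (ep in c(0.01, 0.5, 1, 5, 50, 5000)) {
    cellx <- cell_dielectrics(dielectric_spec(ep, 0), dielectric_spec(ep, 0),
                              1e-12)
    fx <- Re(cm_factor(sphere, cellx, ctx, "a"))
    expect_gte(fx, -0.5)
    expect_lte(fx, 1.0)
  }
})

test_that("cm_factor validates the membrane thickness", {
  geom <- ellipsoid_geometry(4.2e-6, 2.6e-6, 1.3e-6)
  ctx <- excitation_context(1.58e6, dielectric_spec(78, 0.018))
  thick <- cell_dielectrics(dielectric_spec(4.44, 10),
                            dielectric_spec(59, 0.31), 1.4e-6)
  expect_error(cm_factor(geom, thick, ctx, "a"), "thickness")
})
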