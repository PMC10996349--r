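# Double-layer potential and electroosmotic velocity in the tight junction.

test_that("equilibrium potential matches the closed form and is symmetric", {
  p <- double_layer_params()
  prof <- equilibrium_potential(p, n_points = 201L)
  # independent closed-form evaluation (frozen midline value -0.0138154 V)
  expect_equal(prof$potentials_psi[101], -0.0138154, tolerance = 1e-4)
  expect_equal(prof$potentials_psi,
               psi_closed_form(prof$positions_y), tolerance = 1e-12)
  # symmetry about the midline
  expect_equal(prof$potentials_psi, rev(prof$potentials_psi),
               tolerance = 1e-10)
  # bounded by the (overlap-corrected) wall potential
  expect_true(all(abs(prof$potentials_psi) <= abs(p$zeta) * 1.2))
})

test_that("zero zeta potential gives zero potential and zero flow", {
  p0 <- double_layer_params(zeta = 0)
  expect_true(all(equilibrium_potential(p0, 51)$potentials_psi == 0))
  expect_true(all(velocity_profile(p0, 100, 51)$velocities_u == 0))
  co <- fit_coefficients(p0)
  expect_identical(co$avg_velocity_coeff, 0)
  expect_identical(co$max_velocity_coeff, 0)
})

test_that("velocity profile follows the pointwise relation and sign convention", {
  p <- double_layer_params()
  E <- 869.4
  vp <- velocity_profile(p, E, 301L)
  psi <- psi_closed_form(vp$positions_y)
  expect_equal(vp$velocities_u,
               -(p$permittivity * p$zeta * E / p$viscosity) * (1 - psi / p$zeta),
               tolerance = 1e-12)
  # negative zeta + positive field -> field-aligned (positive) midline flow
  expect_gt(vp$velocities_u[151], 0)
  # zero field -> no flow; linearity in E
  expect_true(all(velocity_profile(p, 0, 51)$velocities_u == 0))
  v1 <- velocity_profile(p, 1, 51)$velocities_u
  v10 <- velocity_profile(p, 10, 51)$velocities_u
  expect_equal(v10, 10 * v1, tolerance = 1e-14)
  # symmetric about the midline
  expect_equal(vp$velocities_u, rev(vp$velocities_u), tolerance = 1e-10)
})

test_that("thin double layers recover the Helmholtz-Smoluchowski plateau", {
  p <- double_layer_params(debye_length = 1e-9 / 50)
  hs <- abs(p$permittivity * p$zeta / p$viscosity)  # 1.915e-8 per unit field
  vp <- velocity_profile(p, 1, 1001L)
  expect_rel(max(vp$velocities_u), hs, tol = 0.01)
  # the channel average trails the plateau by ~1/(kappa*h); push further into
  # the thin-layer limit for the same 1% band
  p200 <- double_layer_params(debye_length = 1e-9 / 200)
  expect_rel(abs(average_velocity(p200, 1)), hs, tol = 0.01)
})

test_that("average velocity quadrature is converged and linear in the field", {
  p <- double_layer_params()
  v <- average_velocity(p, 1)
  # refined grid changes the mean by < 0.1%
  mean_at <- function(n) {
    u <- velocity_profile(p, 1, n)$velocities_u
    sum((u[-1] + u[-n]) / 2) / (n - 1)
  }
  expect_rel(mean_at(2001L), mean_at(4001L), tol = 1e-3)
  expect_rel(v, mean_at(8001L), tol = 1e-3)
  expect_identical(average_velocity(p, 0), 0)
  expect_rel(average_velocity(p, 10), 10 * average_velocity(p, 1),
             tol = 1e-12)
})

test_that("stronger double-layer overlap monotonically reduces the mean flow", {
  ratios <- c(0.2, 0.5, 0.9, 1.5)
  v <- vapply(ratios, function(r) {
    abs(average_velocity(double_layer_params(debye_length = r * 1e-9), 1))
  }, numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("velocity coefficients match their frozen derived values", {
  co <- fit_coefficients(double_layer_params())
  # derived: converged trapezoid quadrature of the closed-form profile
  expect_rel(co$avg_velocity_coeff, 3.8471e-9, tol = 1e-3)
  # derived: (eps*zeta/mu)*(1 - psi(h)/zeta) with psi(h) = -0.0138154
  expect_rel(co$max_velocity_coeff, 6.6122e-9, tol = 1e-4)
  expect_true(co$avg_velocity_coeff < co$max_velocity_coeff)
  expect_true(co$max_velocity_coeff <
                abs(7.08e-10 * -0.0211 / 7.80e-4))
})

test_that("flux coefficient is the product of coefficient, opening and L_TJ", {
  co <- structure(list(avg_velocity_coeff = 3.82e-9, max_velocity_coeff = 6.6e-9),
                  class = "eo_coefficients")
  tj <- tj_geometry()
  expect_rel(flux_coefficient(co, tj), 3.82e-9 * 2e-9 * 150000, tol = 1e-12)
  tj2 <- tj_geometry(junction_length_per_area = 300000)
  expect_rel(flux_coefficient(co, tj2), 2 * flux_coefficient(co, tj),
             tol = 1e-12)
  co0 <- structure(list(avg_velocity_coeff = 0, max_velocity_coeff = 0),
                   class = "eo_coefficients")
  expect_identical(flux_coefficient(co0, tj), 0)
})

test_that("invalid double-layer parameters are rejected", {
  expect_error(double_layer_params(half_width_h = 0),
               class = "tdcsflow_invalid_parameter")
  expect_error(double_layer_params(debye_length = -1e-10),
               class = "tdcsflow_invalid_parameter")
  expect_error(equilibrium_potential(double_layer_params(), n_points = 2),
               class = "tdcsflow_invalid_parameter")
  expect_error(tj_geometry(opening_2h = 0),
               class = "tdcsflow_invalid_parameter")
})
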