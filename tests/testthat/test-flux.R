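# Wall current density -> volumetric flux -> net interstitial exchange.

test_that("flux from current reproduces the reference peak fluxes", {
  c1000 <- coupling_constant(teer = 1000)
  # closed network, 1000 TEER: 3.2e-4 A/m^2 -> about 1.0e-9 m^3/s/m^2
  expect_rel(flux_from_current(3.2e-4, 1.15e-12, c1000), 1.0e-9, tol = 0.02)
  expect_identical(flux_from_current(0, 1.15e-12, c1000), 0)
  expect_rel(flux_from_current(4.2e-4, 1.15e-12, c1000), 1.3e-9, tol = 0.03)
})

test_that("the constant chain is associative: Eq(7) x Eq(8) = Eq(9)", {
  const <- coupling_constant(teer = 5000)
  fc <- flux_coefficient(fit_coefficients(double_layer_params()), tj_geometry())
  J <- seq(-5e-4, 5e-4, length.out = 11)
  expect_rel(flux_from_current(J, fc, const),
             fc * tj_field_from_wall_current(J, const), tol = 1e-12)
})

test_that("net exchange aggregates absolute flux per voxel volume and minute", {
  fm <- data.frame(area_m2 = 1e-8, QA = 1e-9)
  expect_equal(net_exchange(fm, 1e-11), 1e-9 * 1e-8 / 1e-11 * 60)  # 6e-5*...
  expect_equal(net_exchange(fm, 1e-11), 6e-5)
  expect_identical(net_exchange(data.frame(area_m2 = 1, QA = 0), 1e-11), 0)
  # linearity and the half-sum convention
  fm2 <- data.frame(area_m2 = c(1e-8, 2e-8), QA = c(1e-9, -5e-10))
  expect_equal(net_exchange(transform(fm2, QA = 2 * QA), 1e-11),
               2 * net_exchange(fm2, 1e-11))
  expect_equal(net_exchange(fm2, 1e-11, convention = "half"),
               net_exchange(fm2, 1e-11) / 2)
  expect_error(net_exchange(fm, 0), class = "tdcsflow_invalid_parameter")
})

test_that("negating wall currents flips fluxes but not the net exchange", {
  sol <- solve_voxel_current(single_vessel_graph(), grid_dims = c(8, 8, 16))
  fc <- 1.15e-12
  const <- coupling_constant(teer = 1000)
  fmap <- wall_flux_map(sol, fc, const)
  expect_equal(sign(fmap$QA), sign(fmap$J_norm))
  sol_neg <- sol
  sol_neg$wall_elements$J_norm <- -sol$wall_elements$J_norm
  fmap_neg <- wall_flux_map(sol_neg, fc, const)
  expect_rel(fmap_neg$QA, -fmap$QA, tol = 1e-12)
  v <- prod(c(0.15e-3, 0.16e-3, 0.43e-3))
  expect_equal(net_exchange(fmap_neg, v), net_exchange(fmap, v))
})

test_that("scaling factors reproduce the reference values within 5%", {
  expect_equal(scaling_factor(1.5e-4, 0.082), 1.9e-3, tolerance = 0.05)
  expect_equal(scaling_factor(5.6e-4, 0.082), 7.0e-3, tolerance = 0.05)
  expect_identical(scaling_factor(0, 0.082), 0)
  expect_error(scaling_factor(1e-4, 0), class = "tdcsflow_invalid_parameter")
})

test_that("synthetic brain fields peak at 0.082 A/m^2 per mA, deterministically", {
  f1 <- synthetic_brain_field(c(12, 12, 12), applied_current_mA = 1, seed = 9)
  expect_equal(max(f1$values), 0.082)
  expect_true(all(f1$values >= 0))
  f2 <- synthetic_brain_field(c(12, 12, 12), applied_current_mA = 2, seed = 9)
  expect_equal(max(f2$values), 0.164)
  expect_equal(f2$values, 2 * f1$values)
  f1b <- synthetic_brain_field(c(12, 12, 12), applied_current_mA = 1, seed = 9)
  expect_identical(f1$values, f1b$values)
  expect_false(identical(
    f1$values, synthetic_brain_field(c(12, 12, 12), seed = 10)$values))
})

test_that("exchange maps are voxelwise products preserving metadata", {
  f <- synthetic_brain_field(c(8, 8, 8), seed = 2)
  k <- 1.83e-3
  m <- scale_brain_map(f, k)
  expect_equal(m$values, f$values * k)
  expect_equal(max(m$values), k * 0.082)
  expect_equal(m$voxel_size_mm, f$voxel_size_mm)
  expect_equal(scale_brain_map(f, 0)$values, array(0, dim = c(8, 8, 8)))
  # uniform field times k is uniform exchange
  uf <- brain_field(array(0.082, dim = c(4, 4, 4)))
  expect_equal(unique(as.vector(scale_brain_map(uf, 1.83e-3)$values)),
               1.5006e-4, tolerance = 1e-4)
  expect_error(brain_field(array(-1, dim = c(2, 2, 2))),
               class = "tdcsflow_invalid_parameter")
})

test_that("volumes round-trip through the portable text format", {
  f <- synthetic_brain_field(c(6, 5, 4), seed = 3)
  path <- withr::local_tempfile(fileext = ".txt")
  write_volume(f, path)
  expect_true(file.exists(paste0(path, ".json")))
  f2 <- read_volume(path)
  expect_s3_class(f2, "brain_field")
  expect_equal(f2$values, f$values, tolerance = 1e-15)
  expect_equal(f2$applied_current_mA, 1)

  m <- scale_brain_map(f, 2e-3)
  mp <- withr::local_tempfile(fileext = ".txt")
  write_volume(m, mp)
  m2 <- read_volume(mp)
  expect_s3_class(m2, "exchange_map")
  expect_equal(m2$values, m$values, tolerance = 1e-15)
  expect_equal(m2$scaling_factor_k, 2e-3)
})

test_that("volumes round-trip through NIfTI when RNifti is available", {
  skip_if_not_installed("RNifti")
  f <- synthetic_brain_field(c(6, 6, 6), seed = 4)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(f, path)
  f2 <- read_volume(path)
  expect_equal(f2$values, f$values, tolerance = 1e-6)
})
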