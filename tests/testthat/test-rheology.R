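test_that("relative viscosity at 45% hematocrit matches its limits and printed values", {
  # wide-tube plateau: both exponentials vanish
  expect_equal(relative_viscosity_45(1e6), 3.2, tolerance = 1e-9)
  expect_equal(relative_viscosity_45(10), 3.892, tolerance = 1e-3 / 3.892)
  expect_equal(relative_viscosity_45(500), 3.110, tolerance = 1e-3)
  expect_error(relative_viscosity_45(1.0), "wall offset")
  expect_error(relative_viscosity_45(-5), "wall offset")
})

test_that("shape exponent has the right limits and is overflow-safe", {
  expect_equal(shape_exponent_c(1e-8), 1, tolerance = 1e-6)
  expect_equal(shape_exponent_c(1e4), -0.8, tolerance = 1e-9)
  # far beyond any physical diameter: must not overflow to NaN
  expect_equal(shape_exponent_c(1e60), -0.8, tolerance = 1e-9)
  expect_equal(shape_exponent_c(10), -1.066, tolerance = 1e-3)
  expect_error(shape_exponent_c(0), "positive")
})

test_that("apparent viscosity reproduces the six published reference cells", {
  # (d, H) grid printed to 3 significant figures, 1e-3 Pa*s
  cells <- rbind(
    c(10, 0.15, 2.24), c(10, 0.45, 5.87), c(10, 0.60, 9.83),
    c(500, 0.15, 1.49), c(500, 0.45, 3.1), c(500, 0.60, 4.76))
  mu <- apparent_viscosity(cells[, 1], cells[, 2]) * 1e3
  expect_equal(round(mu[1:4], 2), cells[1:4, 3])
  expect_equal(round(mu[5], 1), cells[5, 3])
  expect_equal(round(mu[6], 2), cells[6, 3])
})

test_that("apparent viscosity agrees with an independent evaluation of the law", {
  set.seed(7)
  d <- runif(50, 5, 3000); h <- runif(50, 0, 0.8)
  expect_equal(apparent_viscosity(d, h), oracle_mu_a(d, h), tolerance = 1e-12)
})

test_that("at 45% hematocrit the correction factor is exactly 1, whatever C is", {
  # perturbing the shape-exponent coefficients must not move mu_a(d, 0.45)
  base <- rheology_constants()
  warped <- rheology_constants(c_coeffs = c(2.5, -0.01, 1e-9, 8))
  d <- c(8, 30, 200, 900)
  expect_equal(apparent_viscosity(d, 0.45, warped),
               apparent_viscosity(d, 0.45, base), tolerance = 1e-14)
  # and the value reduces to mu_PL * (1 + (mu45 - 1) W) * W
  W <- (d / (d - 1.1))^2
  expect_equal(apparent_viscosity(d, 0.45),
               0.001 * (1 + (relative_viscosity_45(d) - 1) * W) * W,
               tolerance = 1e-14)
})

test_that("zero hematocrit reduces to plasma times the wall factor", {
  expect_equal(apparent_viscosity(500, 0), 0.001 * (500 / 498.9)^2,
               tolerance = 1e-12)
})

test_that("apparent viscosity is monotone in hematocrit and in diameter", {
  h_grid <- seq(0, 0.8, by = 0.05)
  for (d in c(10, 50, 500)) {
    mu <- apparent_viscosity(d, h_grid)
    expect_true(all(diff(mu) > 0))
  }
  # steep decrease from the capillary side down to the minimum (near 30 um
  # at 45% hematocrit); beyond it the curve climbs back toward the plateau
  # but stays well below the 10-um value
  mu_d <- apparent_viscosity(c(10, 20, 30, 100, 500), 0.45)
  expect_true(all(diff(mu_d[1:3]) < 0))
  expect_true(all(mu_d[-1] < mu_d[1]))
})

test_that("raising hematocrit 45% to 60% in a 10 um vessel gives a 1.67-fold rise", {
  fold <- apparent_viscosity(10, 0.60) / apparent_viscosity(10, 0.45)
  expect_equal(fold, 1.67, tolerance = 0.01 / 1.67)
})

test_that("domain guards reject invalid hematocrit and diameters", {
  expect_error(apparent_viscosity(10, 1), "fraction")
  expect_error(apparent_viscosity(10, -0.1), "fraction")
  expect_error(apparent_viscosity(1.1, 0.45), "wall offset")
  expect_error(tube_hematocrit(5.6, 1.2), "fraction")
})

test_that("tube hematocrit follows the Fahraeus relation and its limits", {
  expect_equal(tube_hematocrit(5.6, 0), 0)
  expect_equal(tube_hematocrit(5.6, 1), 1)
  expect_equal(tube_hematocrit(1e5, 0.37), 0.37, tolerance = 1e-6)
  expect_equal(tube_hematocrit(5.6, 0.45), 0.369, tolerance = 1e-3)
  # the reduction: tube below discharge for all physiological tubes
  set.seed(11)
  d <- runif(200, 4, 1000); h <- runif(200, 0, 1)
  expect_true(all(tube_hematocrit(d, h) <= h + 1e-12))
  expect_equal(tube_hematocrit(d, h), oracle_ht(d, h), tolerance = 1e-12)
})

test_that("the published tube-hematocrit triple reproduces at the capillary diameter", {
  ht <- tube_hematocrit(5.6, c(0.15, 0.45, 0.60)) * 100
  expect_equal(round(ht, 1), c(10.8, 36.9, 52.1))
})

test_that("hematocrit bookkeeping equates discharge and systemic values", {
  hs <- hematocrit_set(0.45, "measured", diameter = 5.6)
  expect_equal(hs$h_d, hs$h_sys)
  expect_lt(hs$h_t, hs$h_d)
  expect_error(hematocrit_set(1.4), "fraction")
})

test_that("overriding a rheology constant is recorded in provenance", {
  rc <- rheology_constants(wall_offset = 1.12)
  expect_true("wall_offset" %in% rc$modified)
  expect_length(rheology_constants()$modified, 0)
})
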