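test_that("air density follows the ideal-gas law", {
  expect_equal(air_density(277, 1e5), 1.2579, tolerance = 1e-4)
  expect_equal(air_density(273.15, 287 * 273.15), 1)
  expect_equal(air_density(554, 1e5), air_density(277, 1e5) / 2)
  expect_error(air_density(-1, 1e5), "positive")
  expect_error(air_density(277, 0), "positive")
})

test_that("Sutherland viscosity and conductivity hit their reference points", {
  expect_equal(air_viscosity(273.15), 1.716e-5)
  expect_equal(air_viscosity(277), 1.73499e-5, tolerance = 1e-4)
  expect_equal(air_conductivity(273.15), 0.0241)
  expect_equal(air_conductivity(277), 0.024410, tolerance = 1e-4)
  expect_equal(air_conductivity(297.5), 0.026036, tolerance = 1e-4)
  expect_error(air_viscosity(0), "positive")
  expect_error(air_conductivity(-5), "positive")
})

test_that("property correlations are smooth, positive and monotone on the working range", {
  Ts <- seq(200, 350, by = 1)
  mu <- air_viscosity(Ts)
  k <- air_conductivity(Ts)
  expect_true(all(mu > 0) && all(k > 0))
  expect_true(all(diff(mu) > 0))
  expect_true(all(diff(k) > 0))
})

test_that("air_state assembles a consistent Prandtl number", {
  a <- air_state(277, 1e5)
  expect_s3_class(a, "air_state")
  expect_equal(a$Pr, 0.7150, tolerance = 1e-3)
  # round trip: Pr recomputed from the stored fields is the stored Pr
  expect_identical(a$Pr, a$cp_a * a$mu_a / a$k_a)
  # Pr is nearly constant over the working temperature range
  Pr <- vapply(seq(250, 320, by = 5), function(T) air_state(T, 1e5)$Pr, 0)
  expect_lt(max(abs(Pr - mean(Pr)) / mean(Pr)), 0.03)
})

test_that("material properties are validated", {
  m <- cocoa_butter()
  expect_equal(m$rho, 894)
  expect_equal(m$cp_liquid, 2200)
  expect_equal(m$cp_solid, 1250)
  expect_equal(m$latent_heat, 157000)
  expect_equal(m$T_freeze, 291)
  expect_equal(m$T_solidus, 273)
  expect_error(material_properties(894, 2200, 1250, 157000,
                                   T_freeze = 273, T_solidus = 291, 0.18),
               "T_freeze")
  expect_error(material_properties(-1, 2200, 1250, 157000, 291, 273, 0.18),
               "positive")
  # zero latent heat is a legal material (no phase-change enthalpy)
  expect_silent(material_properties(894, 2200, 1250, 0, 291, 273, 0.18))
})
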