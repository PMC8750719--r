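test_that("solid fraction is the clipped linear-in-temperature closure", {
  expect_equal(solid_fraction(291, cb), 0)
  expect_equal(solid_fraction(273, cb), 1)
  expect_equal(solid_fraction(282, cb), 0.5)
  expect_equal(solid_fraction(300, cb), 0)
  expect_equal(solid_fraction(260, cb), 1)
})

test_that("semisolid heat capacity interpolates with the liquid-core radius", {
  expect_equal(cp_semisolid(0, cb), 2200)
  expect_equal(cp_semisolid(1, cb), 1250)
  expect_equal(cp_semisolid(0.875, cb), 1725)  # a = 0.5 midpoint
  expect_error(cp_semisolid(1.2, cb), "\\[0, 1\\]")
})

test_that("staged energy balance gives the expected instantaneous rates", {
  r1 <- droplet_rate(318, "precooling", 2e-3, cb, Ta = 277, Vdg = 0.83,
                     p = 1e5)
  expect_equal(r1$dT_dt, -6.275, tolerance = 1e-3)
  r2 <- droplet_rate(291, "solidifying", 2e-3, cb, Ta = 277, Vdg = 0.83,
                     p = 1e5)
  expect_equal(r2$dT_dt, -0.4201, tolerance = 1e-3)
  # zero driving force in every stage
  for (st in c("precooling", "solidifying", "tempering")) {
    expect_equal(droplet_rate(282, st, 2e-3, cb, Ta = 282, Vdg = 0.83,
                              p = 1e5)$dT_dt, 0)
  }
})

test_that("frozen-h stage-1 trajectory matches the closed-form exponential", {
  h <- 96.86
  ctl <- solidify_control(h_fixed = h, t_max_s = 30)
  traj <- suppressWarnings(
    simulate_droplet(2e-3, 318, cb, Ta = 277, Vdg = 0.83, p = 1e5,
                     control = ctl))
  s1 <- traj$samples[traj$samples$stage == "precooling", ]
  tau <- cb$rho * cb$cp_liquid * 2e-3 / (6 * h)
  T_exact <- 277 + (318 - 277) * exp(-s1$t_s / tau)
  expect_lt(max(abs(s1$T_K - T_exact) / T_exact), 1e-6)
})

test_that("baseline trajectory has the documented structure", {
  traj <- baseline_traj()
  s <- traj$samples
  expect_true(all(diff(s$t_s) > 0))
  expect_true(all(diff(s$f_solid) >= 0))
  # stages appear in order with no reversals
  stage_idx <- match(s$stage, c("precooling", "solidifying", "tempering"))
  expect_true(all(diff(stage_idx) >= 0))
  # cooling is monotone while above ambient
  expect_true(all(diff(s$T_K) <= 1e-12))
  # solidification never completes at 277 K ambient (ambient sits inside
  # the phase-change range), so there is no tempering stage
  expect_true(is.na(traj$t_solidify_s))
  expect_false("tempering" %in% s$stage)
  expect_false(traj$truncated)
  # event-located onset lands exactly on the threshold
  expect_equal(s$T_K[which(s$stage == "solidifying")[1]], 291,
               tolerance = 1e-6)
})

test_that("latent heat is tracked exactly as m L f_solid", {
  traj <- baseline_traj()
  m <- cb$rho * pi * (2e-3)^3 / 6
  f_end <- traj$samples$f_solid[nrow(traj$samples)]
  expect_equal(traj$q_latent_J, m * cb$latent_heat * f_end,
               tolerance = 1e-12)
  # full solidification releases all the latent heat: 0.5879 J for 2 mm
  cold <- cold_traj()
  expect_equal(cold$q_latent_J, 0.587930, tolerance = 1e-4)
  expect_equal(max(cold$samples$f_solid), 1)
})

test_that("energy audit closes to well under 0.1% of the heat exchanged", {
  expect_lt(energy_audit(baseline_traj())$relative, 1e-3)
  expect_lt(energy_audit(cold_traj())$relative, 1e-3)
})

test_that("stage durations are insensitive to halving the tolerances", {
  tight <- suppressWarnings(simulate_droplet(
    2e-3, 318, cb, Ta = 263, Vdg = 0.83, p = 1e5,
    control = solidify_control(rtol = 5e-9, atol = 5e-9)))
  ref <- cold_traj()
  expect_lt(abs(tight$t_precool_s - ref$t_precool_s) / ref$t_precool_s,
            1e-3)
  expect_lt(abs(tight$t_solidify_s - ref$t_solidify_s) / ref$t_solidify_s,
            1e-3)
})

test_that("degenerate and invalid inputs are handled per contract", {
  # droplet already at ambient: constant-temperature trajectory
  tr <- simulate_droplet(2e-4, 280, cb, Ta = 280, Vdg = 0.2, p = 1e5)
  expect_equal(nrow(tr$samples), 1L)
  expect_equal(tr$samples$T_K, 280)
  expect_equal(tr$rate_initial_K_s, 0)
  expect_error(simulate_droplet(2e-3, 250, cb, Ta = 277, Vdg = 0.83),
               "cooling")
  expect_error(simulate_droplet(-1e-3, 318, cb, Ta = 277, Vdg = 0.83),
               "positive")
  # t_max reached flags truncation instead of erroring
  tr2 <- suppressWarnings(simulate_droplet(
    2e-3, 318, cb, Ta = 277, Vdg = 0.83,
    control = solidify_control(t_max_s = 2)))
  expect_true(tr2$truncated)
})
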