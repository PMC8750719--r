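test_that("packaged validation scenarios return the reference summary shape", {
  v <- run_validation("baseline_277K")
  expect_s3_class(v, "validation_result")
  expect_equal(v$Nu_mean, 7.85, tolerance = 0.05)
  expect_equal(v$h_mean, 96.86, tolerance = 0.05)
  expect_equal(v$rate_initial_K_s, 6.275, tolerance = 1e-3)
  vc <- run_validation("cold_263K")
  expect_equal(vc$t_full_solid_s, 38.06, tolerance = 0.01)
  expect_error(run_validation("warm_300K"))
})

test_that("the 4x2x2 sweep is complete, finite and ordered deterministically", {
  sw <- sweep_grid()
  expect_equal(nrow(sw), 16L)
  expect_true(all(is.finite(sw$t_precool_s)) && all(sw$t_precool_s > 0))
  expect_true(all(is.finite(sw$t_solidify_s)) && all(sw$t_solidify_s > 0))
  # ordering: d outermost, then Ta, then Vdg
  expect_equal(sw$d_um, rep(c(200, 300, 400, 500), each = 4))
  expect_equal(sw$Ta_K, rep(rep(c(220, 270), each = 2), 4))
  expect_equal(sw$Vdg_cm_s, rep(c(20, 100), 8))
  # single-point lists give one record
  one <- run_sweep(d_um = 300, Ta_K = 220, Vdg_cm_s = 100)
  expect_equal(nrow(one), 1L)
  expect_error(run_sweep(d_um = numeric(0)), "non-empty")
})

test_that("sweep times respond monotonically to size, temperature and speed", {
  sw <- sweep_grid()
  for (col in c("t_precool_s", "t_solidify_s")) {
    # larger droplets take longer at every (Ta, Vdg)
    for (Ta in unique(sw$Ta_K)) for (V in unique(sw$Vdg_cm_s)) {
      sub <- sw[sw$Ta_K == Ta & sw$Vdg_cm_s == V, ]
      expect_true(all(diff(sub[order(sub$d_um), col]) > 0))
    }
    # colder ambient is faster at every (d, Vdg)
    for (d in unique(sw$d_um)) for (V in unique(sw$Vdg_cm_s)) {
      sub <- sw[sw$d_um == d & sw$Vdg_cm_s == V, ]
      expect_lt(sub[sub$Ta_K == 220, col], sub[sub$Ta_K == 270, col])
    }
    # faster gas is faster at every (d, Ta)
    for (d in unique(sw$d_um)) for (Ta in unique(sw$Ta_K)) {
      sub <- sw[sw$d_um == d & sw$Ta_K == Ta, ]
      expect_lt(sub[sub$Vdg_cm_s == 100, col], sub[sub$Vdg_cm_s == 20, col])
    }
  }
})

test_that("ambient temperature dominates speed for the solidification time", {
  sw <- sweep_grid()
  for (d in unique(sw$d_um)) {
    sub <- sw[sw$d_um == d, ]
    t_of <- function(Ta, V) sub$t_solidify_s[sub$Ta_K == Ta &
                                             sub$Vdg_cm_s == V]
    rel_Ta <- abs(t_of(270, 20) - t_of(220, 20)) / t_of(270, 20)
    rel_V <- abs(t_of(270, 20) - t_of(270, 100)) / t_of(270, 20)
    expect_gt(rel_Ta, rel_V)
  }
})

test_that("exponential fitting recovers exact generators and rejects bad input", {
  d <- c(200, 300, 400, 500)
  t_exact <- 0.5 * exp(0.002 * d)
  fit <- fit_exponential(d, t_exact)
  expect_equal(fit$prefactor, 0.5, tolerance = 1e-10)
  expect_equal(fit$rate, 0.002, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_exponential(c(200, 300), c(1, 2)), "3 distinct")
  expect_error(fit_exponential(d, c(1, 2, -1, 3)), "positive")
})

test_that("fits on the package's own sweep are tight", {
  fits <- fit_sweep(sweep_grid())
  expect_equal(nrow(fits), 4L)
  expect_true(all(fits$r2_pre > 0.98))
  expect_true(all(fits$r2_sol > 0.98))
  expect_true(all(fits$A_s > 0) && all(fits$B_s > 0))
  ref <- reference_fit_constants()
  expect_equal(sort(names(ref)[1:4]), sort(c("Ta_K", "Vdg_cm_s", "A_s", "B_s")))
  expect_equal(nrow(ref), 4L)
})

test_that("the lumped-capacitance h estimator inverts a frozen-h cooling run", {
  h_true <- 96.86
  ctl <- solidify_control(h_fixed = h_true, t_max_s = 30)
  traj <- suppressWarnings(simulate_droplet(2e-3, 318, cb, Ta = 277,
                                            Vdg = 0.83, p = 1e5,
                                            control = ctl))
  s1 <- traj$samples[traj$samples$stage == "precooling", ]
  n <- nrow(s1)
  h_est <- gwie_h(cb$cp_liquid, cb$rho, 2e-3, T0 = 318, Td = s1$T_K[n],
                  Ta = 277, t = s1$t_s[n])
  expect_lt(abs(h_est - h_true) / h_true, 0.005)
  # direct arithmetic example
  expect_equal(gwie_h(2200, 894, 2e-3, 318, 291, 277, 7.28), 96.77,
               tolerance = 1e-3)
  expect_error(gwie_h(2200, 894, 2e-3, 318, 276, 277, 7), "Ta")
  expect_equal(gwie_h(2200, 894, 2e-3, 318, 291, 277, 14.56),
               gwie_h(2200, 894, 2e-3, 318, 291, 277, 7.28) / 2)
})

test_that("the Nusselt estimator is the exact inverse of htc", {
  expect_equal(gwie_nu(96.86, 2e-3, 0.0244), 7.939, tolerance = 1e-3)
  expect_equal(gwie_nu(htc(7.85, 0.0244, 2e-3), 2e-3, 0.0244), 7.85)
  expect_equal(gwie_nu(0, 2e-3, 0.0244), 0)
  expect_error(gwie_nu(96.86, 2e-3, 0), "positive")
})
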