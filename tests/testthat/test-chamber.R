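test_that("gas-cell energy balance has the right equilibrium and sign", {
  air <- air_state(277, 1e5)
  cell <- gas_cell(V_cell = 1e-5, T_in = 277, v_in = 0.83)
  expect_equal(gas_cell_rhs(cell, q_drop = 0, air), 0)
  expect_gt(gas_cell_rhs(cell, q_drop = 0.5, air), 0)
  # steady state offset: T_local - T_in = q_drop / (mdot cp)
  mdot <- air$rho_a * 0.83 * pi * 0.0032^2 / 4
  q <- 0.2
  cell_ss <- gas_cell(V_cell = 1e-5, T_in = 277, v_in = 0.83,
                      T_local = 277 + q / (mdot * air$cp_a))
  expect_equal(gas_cell_rhs(cell_ss, q_drop = q, air), 0, tolerance = 1e-12)
  expect_error(gas_cell(V_cell = 0, T_in = 277, v_in = 0.83), "positive")
})

test_that("an effectively infinite cell reproduces the uncoupled run", {
  cell <- gas_cell(V_cell = 1e6, T_in = 277, v_in = 0.83)
  tc <- suppressWarnings(simulate_coupled(2e-3, 318, cb, cell = cell,
                                          Vdg = 0.83, p = 1e5))
  tu <- baseline_traj()
  T_ref <- stats::approx(tu$samples$t_s, tu$samples$T_K,
                         xout = pmin(tc$samples$t_s, tu$t_end_s))$y
  expect_lt(max(abs(tc$samples$T_K - T_ref)), 0.01)
})

test_that("a very high flush rate also reproduces the uncoupled run", {
  cell <- gas_cell(V_cell = 1e-5, T_in = 277, v_in = 500, d_hole = 0.05)
  tc <- suppressWarnings(simulate_coupled(2e-3, 318, cb, cell = cell,
                                          Vdg = 0.83, p = 1e5))
  tu <- baseline_traj()
  T_ref <- stats::approx(tu$samples$t_s, tu$samples$T_K,
                         xout = pmin(tc$samples$t_s, tu$t_end_s))$y
  expect_lt(max(abs(tc$samples$T_K - T_ref)), 0.01)
})

test_that("finite-cell coupling warms the local gas and slows every stage", {
  cell <- gas_cell(V_cell = 3e-6, T_in = 263, v_in = 0.83)
  tc <- suppressWarnings(simulate_coupled(2e-3, 318, cb, cell = cell,
                                          Vdg = 0.83, p = 1e5))
  tu <- cold_traj()
  expect_gt(tc$t_precool_s, tu$t_precool_s)
  expect_gt(tc$t_solidify_s, tu$t_solidify_s)
  expect_gt(max(tc$samples$T_local_K), 263)
  # droplet + cell + outflow energy closes
  expect_lt(tc$cell_residual_rel, 1e-3)
})
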