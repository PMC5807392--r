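p_default <- mcell_params()

test_that("default parameters reproduce the reference set", {
  expect_equal(p_default$g_Ca, 4)
  expect_equal(p_default$eps, 0.00033)
  expect_equal(p_default$v_K, -84)
  expect_equal(p_default$rho, 8400)
  expect_equal(p_default$sigma_s, 4)
  expect_equal(p_default$s2, 0.029)
  expect_equal(phenotype_params("dominant")$ag_max, 41.5)
  expect_equal(phenotype_params("subordinate")$ag_max, 43.5)
  expect_error(mcell_params(rho = -1), "strictly positive")
  expect_error(mcell_params(g_K = -1), "nonnegative")
  expect_error(mcell_params(bogus = 1), "unknown parameter")
})

test_that("activation curves hit their half-activation points", {
  ac <- activation_curves(p_default$v1, p_default)
  expect_equal(ac$m_inf, 0.5)
  ac <- activation_curves(p_default$v3, p_default)
  expect_equal(ac$n_inf, 0.5)
  expect_equal(ac$tau_n, 1)
  ac <- activation_curves(p_default$theta_s, p_default)
  expect_equal(ac$s_inf, 0.5)
})

test_that("gating curves are bounded and n_inf matches the hand-computed value", {
  v <- seq(-100, 60, by = 2.5)
  ac <- activation_curves(v, p_default)
  expect_true(all(ac$m_inf >= 0 & ac$m_inf <= 1))
  expect_true(all(ac$n_inf >= 0 & ac$n_inf <= 1))
  expect_true(all(ac$s_inf >= 0 & ac$s_inf <= 1))
  expect_true(all(ac$tau_n > 0))
  expect_true(all(diff(ac$m_inf) > 0))  # sigmoidal, increasing
  # frozen direct evaluation: 0.5 * (1 + tanh((-34.32 - 12)/17))
  expect_equal(activation_curves(-34.32, p_default)$n_inf, 0.0042804,
               tolerance = 1e-4)
})

test_that("membrane currents match their algebraic forms", {
  st <- cell_state(v = -84, n = 0.3, Ca = 5, s = 0, E_net = 1)
  cur <- membrane_currents(st, other_s = 0, p_default)
  expect_equal(cur$I_K, 0)     # zero driving force at v = v_K
  expect_equal(cur$I_KCa, 0)

  st <- cell_state(v = -34, n = 0.01, Ca = 10, s = 0, E_net = 1)
  cur <- membrane_currents(st, other_s = 0, p_default)
  expect_equal(cur$I_KCa, 0.25 * 0.5 * (-34 + 84))  # half-saturated at Ca = k1

  # frozen hand evaluation at the reference dominant-like rest point
  st <- cell_state(v = -34.32, n = 0.00427, Ca = 3.05, s = 0, E_net = 0.964)
  cur <- membrane_currents(st, other_s = 0, p_default)
  total <- -(cur$I_Ca + cur$I_K + cur$I_KCa + cur$I_L)
  expect_equal(total, -40.7732, tolerance = 1e-4)
  # ... which balances I_app = I0 + w_M * E_net of about 41
  expect_equal(total + 40.5 + 0.5 * 0.964, 0, tolerance = 0.3)
})

test_that("adaptation target is reciprocal in calcium", {
  p40 <- mcell_params(ag_max = 40)
  expect_equal(net_excitation_target(0, p40), 1)
  p415 <- mcell_params(ag_max = 41.5)
  expect_equal(net_excitation_target(3.05, p415), 0.963995, tolerance = 1e-5)
  # strictly decreasing, bounded by ag_max/k2
  Ca <- seq(0, 10, by = 0.5)
  tg <- net_excitation_target(Ca, p415)
  expect_true(all(diff(tg) < 0))
  expect_true(all(tg <= p415$ag_max / p415$k2))
  expect_error(net_excitation_target(-1, p40), ">= 0")
})

test_that("vector field special cases hold", {
  # calcium equation with no influx and no calcium is stationary
  p0 <- mcell_params(g_Ca = 0)
  cs <- circuit_state(cell_state(v = -40, n = 0.1, Ca = 0, s = 0.1, E_net = 1))
  d <- circuit_derivatives(cs, p0)
  expect_equal(unname(d[["Ca1"]]), 0)

  # invalid state is signalled, not propagated
  bad <- structure(setNames(c(-40, 0.1, -0.5, 0.1, 1, -40, 0.1, 3, 0.1, 1),
                            mcellhab:::state_names), class = "circuit_state")
  expect_error(circuit_derivatives(bad, p_default), "negative calcium")
})

test_that("vector field is equivariant under swapping cells with drives", {
  c1 <- cell_state(v = -30, n = 0.02, Ca = 3.1, s = 0.05, E_net = 0.95)
  c2 <- cell_state(v = -50, n = 0.005, Ca = 2.2, s = 0.01, E_net = 1.1)
  d12 <- circuit_derivatives(circuit_state(c1, c2), p_default,
                             drive1 = 4.5, drive2 = 0)
  d21 <- circuit_derivatives(circuit_state(c2, c1), p_default,
                             drive1 = 0, drive2 = 4.5)
  expect_equal(unname(d12[1:5]), unname(d21[6:10]))
  expect_equal(unname(d12[6:10]), unname(d21[1:5]))
})

test_that("gating and adaptation variables stay in their invariant sets", {
  p <- mcell_params(ag_max = 43.5)
  starts <- list(c(-60, 0.5, 0.5, 0.9, 0.3), c(0, 0.01, 6, 0.01, 1.05),
                 c(-20, 0.2, 1, 0.5, 0.2))
  for (s0 in starts) {
    cs <- circuit_state(cell_state(s0[1], s0[2], s0[3], s0[4], s0[5]))
    tr <- integrate_circuit(cs, p, train = pulse_train(50, 2, 4, 4.5, 2),
                            t_end = 3000, step = 0.02, sample_by = 1)
    expect_true(all(tr$n1 >= 0 & tr$n1 <= 1))
    expect_true(all(tr$s1 >= 0 & tr$s1 <= 1))
    expect_true(all(tr$Ca1 >= -1e-9))
    expect_true(all(tr$E_net1 > 0 &
                      tr$E_net1 <= pmax(s0[5], p$ag_max / p$k2) + 1e-9))
  }
})
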