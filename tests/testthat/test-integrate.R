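test_that("an exact fixed point is preserved by the integrator", {
  fp <- oracle_toggle_fixed_points(10, 1)$upper
  tr <- integrate_circuit(circuit_toggle(), fp, 0, sim_config())
  expect_true(tr$converged)
  expect_lt(max(abs(tr$final - fp)), 1e-6)
})

test_that("toggle trajectories reach the oracle fixed point", {
  fp <- oracle_toggle_fixed_points(10, 1)
  cfg <- sim_config(steady_tol = 1e-8)
  tr <- integrate_circuit(circuit_toggle(), c(10, 0), 0, cfg)
  expect_true(tr$converged)
  expect_lt(max(abs(tr$final - fp$upper)), 1e-6)
  expect_equal(unname(tr$final["A"]), 9.898979, tolerance = 1e-5)
  expect_equal(unname(tr$final["B"]), 0.1010205, tolerance = 1e-4)
})

test_that("halving the step size moves the final state by < 1e-6", {
  for (case in list(list(m = circuit_toggle(), init = c(10, 0), stim = 0),
                    list(m = circuit_self_activation(), init = 5, stim = 33),
                    list(m = circuit_standin(1), init = c(5, 0, 0), stim = 33))) {
    f1 <- integrate_circuit(case$m, case$init, case$stim, sim_config(h = 0.01))$final
    f2 <- integrate_circuit(case$m, case$init, case$stim, sim_config(h = 0.005))$final
    expect_lt(max(abs(f1 - f2)), 1e-6)
  }
})

test_that("simulated steady states stay non-negative", {
  set.seed(42)
  cfg <- sim_config()
  for (i in 1:20) {
    init <- runif(2, 0, 12)
    tr <- integrate_circuit(circuit_toggle(), init, 0, cfg)
    expect_gte(min(tr$final), -cfg$steady_tol)
    expect_true(all(tr$states >= -cfg$steady_tol))
  }
})

test_that("random off-diagonal toggle states are captured by the two attractors", {
  fp <- oracle_toggle_fixed_points(10, 1)
  set.seed(7)
  inits <- matrix(runif(400, 0, 12), 200, 2)
  inits <- inits[abs(inits[, 1] - inits[, 2]) > 0.05, ]
  m <- circuit_toggle()
  res <- switchscan:::rk4_batch(m, inits, 0, m$params, h = 0.01, t_end = 500,
                                steady_tol = 1e-8)
  d_up <- sqrt((res$final[, 1] - fp$upper["A"])^2 + (res$final[, 2] - fp$upper["B"])^2)
  d_lo <- sqrt((res$final[, 1] - fp$lower["A"])^2 + (res$final[, 2] - fp$lower["B"])^2)
  expect_gte(mean(pmin(d_up, d_lo) < 1e-6), 0.99)
})

test_that("a diverging system raises an integration-failure error", {
  boom <- switchscan:::new_circuit_model(
    "boom", "X", function(state, stimulus, params) state^2, list(r = 1))
  expect_error(
    integrate_circuit(boom, 10, 0, sim_config(t_end = 50)),
    class = "switchscan_integration_error"
  )
})

test_that("input validation catches bad initial states", {
  expect_error(integrate_circuit(circuit_toggle(), c(-1, 0), 0, sim_config()),
               class = "switchscan_validation_error")
  expect_error(integrate_circuit(circuit_toggle(), c(1, 2, 3), 0, sim_config()),
               class = "switchscan_validation_error")
  expect_error(integrate_circuit(circuit_toggle(), c(1, 1), Inf, sim_config()),
               class = "switchscan_validation_error")
})

test_that("self-activation switch shows a hysteresis window", {
  hw <- hysteresis_sweep(circuit_self_activation(), seq(0, 60, length.out = 61))
  expect_gt(hw$window_width, 0)
  # window should bracket the full-derepression stimulus 1/K
  expect_lt(hw$window_low, 1 / 0.03)
  expect_gt(hw$window_high, 1 / 0.03)
})
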