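test_that("constructors reject non-positive parameters", {
  expect_error(circuit_self_activation(p = 0), class = "switchscan_validation_error")
  expect_error(circuit_self_activation(K = -1), class = "switchscan_validation_error")
  expect_error(circuit_toggle(alpha = 0), class = "switchscan_validation_error")
  expect_error(circuit_standin(n_graded = 0), class = "switchscan_validation_error")
  expect_error(circuit_standin(d_eff = -2), class = "switchscan_validation_error")
})

test_that("self-activation vector field matches the printed model", {
  m <- circuit_self_activation(p = 4, K = 0.03, d = 0.1)
  # zero state kills the quadratic self-activation term at any stimulus
  expect_equal(drop(m$rhs(matrix(0, 1, 1), 7, m$params)), 0, ignore_attr = TRUE)
  # Ki = 1 makes R = 0, so the repression factor is 1
  i_star <- 1 / m$params$K
  A <- 1.7
  expected <- 4 * A^2 / (1 + A^2) - A / 2.5 - 0.1 * A
  expect_equal(drop(m$rhs(matrix(A, 1, 1), i_star, m$params)), expected,
               tolerance = 1e-12, ignore_attr = TRUE)
  # derivative at zero state is >= 0 for every state (non-negativity)
  expect_gte(drop(m$rhs(matrix(0, 1, 1), 0, m$params)), 0)
})

test_that("default self-activation parameters give a bistable regime", {
  # brute-force root scan: at full derepression (R = 0) there are two stable
  # steady states (OFF at 0 and ON near 7.87) separated by a threshold
  roots <- oracle_selfact_roots(R = 0)
  expect_gte(sum(roots$stable), 2)
  expect_equal(sort(roots$roots[roots$stable])[1], 0, tolerance = 1e-3)
  expect_equal(sort(roots$roots[roots$stable])[2], 7.8726, tolerance = 1e-3)
})

test_that("toggle-switch field is symmetric on the diagonal", {
  m <- circuit_toggle(alpha = 10, d = 1)
  for (a in c(0.5, 2, 9)) {
    dv <- m$rhs(matrix(c(a, a), 1, 2), 0, m$params)
    expect_equal(dv[1, 1], dv[1, 2])
  }
  # off-diagonal: printed equations exactly
  dv <- m$rhs(matrix(c(3, 1), 1, 2), 0, m$params)
  expect_equal(dv[1, 1], 10 / (1 + 1^2) - 3)
  expect_equal(dv[1, 2], 10 / (1 + 3^2) - 1)
})

test_that("stand-in network separates switch-like and graded responses", {
  m <- circuit_standin(n_graded = 2)
  # zero stimulus and zero state is a fixed point
  expect_equal(max(abs(m$rhs(matrix(0, 1, 4), 0, m$params))), 0)
  cfg <- sim_config(t_end = 400)
  # graded genes settle at a level proportional to the stimulus
  s2 <- integrate_circuit(m, rep(0, 4), 2, cfg)$final[["graded1"]]
  s4 <- integrate_circuit(m, rep(0, 4), 4, cfg)$final[["graded1"]]
  expect_equal(s4 / s2, 2, tolerance = 1e-4)
  # stimulus sweep from an elevated initial state: the switch gene jumps
  # discontinuously into its ON window, graded genes move smoothly
  stimuli <- seq(0.1, 60, length.out = 200)
  sw <- sweep_steady_states(m, stimuli, c(5, 0, 0, 0), cfg)
  jumps <- function(state) {
    lv <- sw$level[sw$state == state]
    abs(diff(lv))
  }
  j_switch <- jumps("switch")
  j_graded <- jumps("graded1")
  expect_gt(max(j_switch), 10 * max(median(j_switch), 1e-6))
  expect_lt(max(j_graded), 10 * max(median(j_graded), 1e-6))
})
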