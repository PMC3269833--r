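test_that("clone averaging degenerates to a single trajectory when noiseless", {
  m <- circuit_toggle()
  cfg0 <- sim_config(cells_per_clone = 5, cell_cv = 0)
  avg <- sample_clone_average(m, c(8, 1), 0, cfg0)
  single <- integrate_circuit(m, c(8, 1), 0, cfg0)$final
  expect_equal(unclass(avg)[1:2], unclass(single)[1:2], tolerance = 1e-12,
               ignore_attr = TRUE)
  # one cell: one draw, returned directly
  cfg1 <- sim_config(cells_per_clone = 1, cell_cv = 0)
  avg1 <- sample_clone_average(m, c(8, 1), 0, cfg1)
  expect_equal(unclass(avg1)[1:2], unclass(single)[1:2], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("population averaging across a separatrix-straddling clone is graded", {
  # a clone centred on the toggle diagonal sends cells to both attractors;
  # the clone average then sits strictly between the two attractor levels,
  # masking the single-cell all-or-none response
  fp <- oracle_toggle_fixed_points(10, 1)
  cfg <- sim_config(cells_per_clone = 40, cell_cv = 0.2, seed = 1)
  avg <- switchscan:::with_seed(1, {
    sample_clone_average(circuit_toggle(), c(6, 6), 0, cfg)
  })
  for (g in c("A", "B")) {
    lo <- min(fp$upper[g], fp$lower[g])
    hi <- max(fp$upper[g], fp$lower[g])
    expect_gt(avg[[g]], lo + 0.5)
    expect_lt(avg[[g]], hi - 0.5)
  }
})

test_that("noiseless configuration yields identical clone columns", {
  ds <- simulate_expression(
    circuit_toggle(),
    sim_config(n_clones = 5, param_cv = 0, cell_cv = 0,
               init_low = 5, init_high = 5 + 1e-9, seed = 3),
    stimulus_sampler = stimulus_constant(0)
  )
  spread <- apply(ds$expression, 1, function(r) diff(range(r)))
  expect_lt(max(spread), 1e-6)
})

test_that("dataset generation is a pure function of the seed", {
  cfg <- sim_config(n_clones = 15, seed = 99)
  ds1 <- simulate_expression(circuit_toggle(), cfg, extra_graded = 1, extra_noise = 1)
  ds2 <- simulate_expression(circuit_toggle(), cfg, extra_graded = 1, extra_noise = 1)
  expect_identical(ds1$expression, ds2$expression)
  expect_identical(ds1$annotations, ds2$annotations)
  ds3 <- simulate_expression(circuit_toggle(), sim_config(n_clones = 15, seed = 100),
                             extra_graded = 1, extra_noise = 1)
  expect_false(identical(ds1$expression, ds3$expression))
})

test_that("dataset carries coherent truth labels and annotations", {
  ds <- simulate_expression(circuit_toggle(), sim_config(n_clones = 10, seed = 2),
                            extra_graded = 2, extra_noise = 3)
  expect_identical(ds$truth$gene_id, rownames(ds$expression))
  expect_identical(ds$annotations$sample_id, colnames(ds$expression))
  expect_setequal(ds$truth$gene_id[ds$truth$is_switch], c("A", "B"))
  expect_equal(sum(ds$truth$circuit_role == "graded"), 2)
  expect_equal(sum(ds$truth$circuit_role == "noise"), 3)
  expect_true(all(is.finite(ds$expression)))
  expect_gte(ds$converged_fraction, 0.9)
})

test_that("clone count below 2 is rejected", {
  expect_error(
    simulate_expression(circuit_toggle(), sim_config(n_clones = 1, seed = 1)),
    class = "switchscan_validation_error"
  )
})
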