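test_that("single-Gaussian fit matches the closed-form likelihood", {
  expect_error(fit_single_gaussian(c(-1, 1)), class = "switchscan_insufficient_data")
  f <- fit_single_gaussian(c(-1, 0, 1))
  expect_equal(f$means, 0)
  expect_equal(f$variances, 2 / 3)
  expect_equal(f$log_likelihood, -(3 / 2) * (log(2 * pi * 2 / 3) + 1), tolerance = 1e-12)
  expect_equal(f$aic, oracle_single_aic(c(-1, 0, 1)), tolerance = 1e-12)
  # aic = 2k - 2 logL exactly
  expect_identical(f$aic, 2 * 2 - 2 * f$log_likelihood)
})

test_that("single-Gaussian fit transforms correctly under affine maps", {
  set.seed(8)
  x <- rnorm(40, 2, 1.5)
  f <- fit_single_gaussian(x)
  g <- fit_single_gaussian(3 * x + 5)
  expect_equal(g$means, 3 * f$means + 5)
  expect_equal(g$variances, 9 * f$variances)
  expect_equal(g$log_likelihood, f$log_likelihood - 40 * log(3), tolerance = 1e-9)
  expect_equal(g$aic, f$aic + 80 * log(3), tolerance = 1e-9)
})

test_that("zero-variance input gets a floored variance and a flag", {
  f <- fit_single_gaussian(rep(2, 10))
  expect_true(f$floored)
  expect_true(is.finite(f$aic))
})

test_that("EM recovers the parameters of a well-separated mixture", {
  set.seed(11)
  x <- c(rnorm(500, 0), rnorm(500, 6))
  f <- fit_two_gaussian_em(x, seed = 11)
  expect_lt(abs(f$means[1] - 0), 0.2)
  expect_lt(abs(f$means[2] - 6), 0.2)
  expect_lt(abs(f$weights[2] - 0.5), 0.05)
  expect_true(f$converged)
  expect_equal(sum(f$weights), 1, tolerance = 1e-12)
  # components come back sorted by mean
  expect_lt(f$means[1], f$means[2])
})

test_that("EM log-likelihood trace is non-decreasing", {
  set.seed(4)
  for (x in list(c(rnorm(60), rnorm(60, 3)), rnorm(80), rexp(50))) {
    f <- fit_two_gaussian_em(x, seed = 4)
    expect_gte(min(diff(f$trace)), -1e-8)
  }
})

test_that("the collapsed restart bounds the mixture likelihood from below", {
  # logL(2-comp) >= logL(1-comp) on any input, hence delta AIC >= -6
  set.seed(21)
  inputs <- list(rnorm(50), rexp(50), rt(50, df = 3), rep(1.5, 20),
                 c(rep(0, 30), 1e-4 * rnorm(30)), runif(100))
  for (x in inputs) {
    f1 <- fit_single_gaussian(x)
    f2 <- fit_two_gaussian_em(x, seed = 21)
    expect_gte(f2$log_likelihood, f1$log_likelihood - 1e-9)
  }
})

test_that("EM reports non-convergence but still returns the best iterate", {
  set.seed(9)
  x <- c(rnorm(100), rnorm(100, 2))
  expect_warning(
    f <- fit_two_gaussian_em(x, restarts = 3, max_iter = 1, seed = 9),
    class = "switchscan_em_convergence_warning"
  )
  expect_false(f$converged)
  expect_true(is.finite(f$aic))
})

test_that("EM attains at least the brute-force grid likelihood", {
  set.seed(14)
  for (r in 1:5) {
    n <- sample(10:30, 1)
    x <- if (r %% 2 == 0) rnorm(n) else c(rnorm(ceiling(n / 2)), rnorm(floor(n / 2), 4))
    f <- fit_two_gaussian_em(x, seed = r)
    expect_gte(f$log_likelihood, oracle_grid_mixture_loglik(x) - 1e-3)
  }
})

test_that("EM log-likelihood matches an independent EM route on separated data", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(31)
  x <- c(rnorm(300, 0, 1), rnorm(200, 7, 1.3))
  f <- fit_two_gaussian_em(x, seed = 31)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(f$log_likelihood, mc$loglik, tolerance = 1e-3)
})

test_that("delta AIC separates bimodal from unimodal profiles", {
  set.seed(3)
  bim <- c(rnorm(100, 0), rnorm(100, 10))
  uni <- rnorm(200, 5)
  fb <- delta_aic(bim, seed = 3)
  fu <- delta_aic(uni, seed = 3)
  expect_gt(fb$delta_aic, 50)
  expect_lt(fu$delta_aic, 6)
  expect_identical(fb$delta_aic, fb$fit1$aic - fb$fit2$aic)
  # the high mode is the larger-mean component and collects the upper points
  expect_true(all(fb$mode_assignment[bim > 8] == "high"))
  expect_true(all(fb$mode_assignment[bim < 2] == "low"))
})

test_that("delta AIC and mode structure are invariant under affine maps", {
  set.seed(6)
  x <- c(rnorm(80), rnorm(80, 4))
  f <- delta_aic(x, seed = 6)
  for (ab in list(c(3, 5), c(0.2, -1), c(-2, 1))) {
    g <- delta_aic(ab[1] * x + ab[2], seed = 6)
    expect_equal(g$delta_aic, f$delta_aic, tolerance = 1e-6)
    # fitted-parameter functionals wiggle at the EM tolerance, not 1e-6
    expect_equal(g$mixture_separation, f$mixture_separation, tolerance = 1e-3)
    flip <- ab[1] < 0
    expect_identical(g$mode_assignment,
                     if (flip) ifelse(f$mode_assignment == "high", "low", "high")
                     else f$mode_assignment)
  }
})

test_that("duplicated constant data collapses to the single-Gaussian solution", {
  f <- delta_aic(rep(2, 40), seed = 17)
  expect_equal(f$delta_aic, -6, tolerance = 1e-9)
  expect_true(f$fit1$floored)
})

test_that("median delta AIC grows with the true mode separation", {
  seps <- c(0, 2, 4, 6, 8)
  med <- vapply(seps, function(s) {
    d <- vapply(1:20, function(r) {
      set.seed(1000 * s + r)
      x <- c(rnorm(100, 0), rnorm(100, s))
      delta_aic(x, seed = r)$delta_aic
    }, numeric(1))
    median(d)
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
})

test_that("matrix scoring is exchangeable, ranked, and reports failures", {
  set.seed(5)
  m <- rbind(
    bimodal = c(rnorm(50, 0), rnorm(50, 8)),
    flat = rnorm(100, 3),
    broken = c(rnorm(4), rep(NA, 96))
  )
  colnames(m) <- sprintf("s%03d", 1:100)
  sc <- score_bimodality(m, seed = 5)
  expect_equal(sc$gene_id[sc$rank == 1], "bimodal")
  expect_true(is.na(sc$delta_aic[sc$gene_id == "broken"]))
  expect_match(sc$reason[sc$gene_id == "broken"], "at least 6")
  # permuting sample order leaves every delta AIC unchanged
  perm <- sample(ncol(m))
  sc2 <- score_bimodality(m[, perm], seed = 5)
  expect_equal(sc2$delta_aic, sc$delta_aic, tolerance = 1e-9)
  expect_error(score_bimodality(m[, 1:5]), class = "switchscan_validation_error")
})

test_that("toggle genes dominate the delta-AIC ranking of a planted dataset", {
  ds <- simulate_expression(circuit_toggle(),
                            sim_config(n_clones = 100, param_cv = 0.2, seed = 7),
                            extra_graded = 3, extra_noise = 10)
  sc <- score_bimodality(ds$expression, seed = 7)
  toggle_ranks <- sc$rank[sc$gene_id %in% c("A", "B")]
  expect_true(all(toggle_ranks <= 2))
  graded <- max(sc$delta_aic[grepl("graded", sc$gene_id)])
  expect_gt(min(sc$delta_aic[sc$gene_id %in% c("A", "B")]), graded)
})
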