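# Independent oracles used to freeze expected values. Each one takes a route
# that shares no code with the implementation it checks.

# toggle-switch attractors by fixed-point iteration of the nullcline maps
# A = alpha/(1+B^2), B = alpha/(1+A^2), started from (alpha, 0)
oracle_toggle_fixed_points <- function(alpha = 10, d = 1, tol = 1e-10) {
  a <- alpha / d
  A <- a
  B <- 0
  repeat {
    A2 <- a / (1 + B^2)
    B2 <- a / (1 + A2^2)
    if (max(abs(c(A2 - A, B2 - B))) < tol) break
    A <- A2
    B <- B2
  }
  list(upper = c(A = A2, B = B2), lower = c(A = B2, B = A2))
}

# steady states of the self-activation switch at fixed repressor level R by a
# brute-force sign-change scan of dA/dt on a fine grid; returns roots and
# their stability (sign of the slope)
oracle_selfact_roots <- function(p = 4, K = 0.03, d = 0.1, R = 0,
                                 a_max = 50, n_grid = 1e5) {
  f <- function(A) p * A^2 / (1 + A^2) / (1 + R^2) - A / 2.5 - d * A
  grid <- seq(0, a_max, length.out = n_grid)
  v <- f(grid)
  idx <- which(v[-1] * v[-n_grid] < 0)
  roots <- (grid[idx] + grid[idx + 1]) / 2
  if (abs(v[1]) < 1e-12) roots <- c(0, roots) # A = 0 is always a root
  h <- grid[2] - grid[1]
  stable <- vapply(roots, function(r) f(r + h) < f(r - h) && f(r + h) < 0, logical(1))
  list(roots = roots, stable = stable)
}

# closed-form single-Gaussian AIC: 4 + n (ln(2 pi sigma_hat^2) + 1)
oracle_single_aic <- function(x) {
  n <- length(x)
  s2 <- mean((x - mean(x))^2)
  4 + n * (log(2 * pi * s2) + 1)
}

# best two-component mixture log-likelihood over a coarse brute-force grid on
# (weight, mu1, mu2, sigma1, sigma2); independent of EM
oracle_grid_mixture_loglik <- function(x, n_mu = 12, n_sigma = 4, n_w = 5) {
  mus <- seq(min(x), max(x), length.out = n_mu)
  s_all <- sqrt(mean((x - mean(x))^2))
  sigmas <- s_all * c(0.15, 0.4, 0.7, 1)[seq_len(n_sigma)]
  ws <- seq(0.1, 0.9, length.out = n_w)
  pars <- expand.grid(mu1 = mus, s1 = sigmas, mu2 = mus, s2 = sigmas)
  d1 <- outer(x, seq_len(nrow(pars)),
              function(xi, j) dnorm(xi, pars$mu1[j], pars$s1[j]))
  d2 <- outer(x, seq_len(nrow(pars)),
              function(xi, j) dnorm(xi, pars$mu2[j], pars$s2[j]))
  best <- -Inf
  for (w in ws) {
    ll <- colSums(log((1 - w) * d1 + w * d2))
    best <- max(best, max(ll, na.rm = TRUE))
  }
  best
}

# hypergeometric upper-tail probability by direct combinatorial enumeration
oracle_hyper_tail <- function(overlap, category_size, mode_size, total) {
  j <- seq(overlap, min(category_size, mode_size))
  sum(choose(category_size, j) * choose(total - category_size, mode_size - j)) /
    choose(total, mode_size)
}
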