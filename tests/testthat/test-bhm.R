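test_that("the joint objective matches a term-by-term dense evaluation", {
  for (seed in 1:5) {
    p <- 5
    W <- rand_sym(p, seed)
    S <- rand_sym(p, seed + 100)
    Omega <- rand_spd(p, seed + 200)
    lam <- 0.3
    # independent evaluation: explicit inverse, explicit trace, explicit det
    Oi <- solve(Omega)
    ref <- sum((W - S)^2) +
      lam * (sum(diag(Oi %*% W %*% Oi %*% t(W))) +
               p * log(det(Omega)))
    expect_equal(bhm_objective(W, Omega, S, lam), ref, tolerance = 1e-10)
  }
})

test_that("objective simplifies correctly for identity Omega", {
  S <- rand_sym(6, seed = 3)
  I6 <- diag(6)
  lam <- 0.7
  # W = S: only the prior trace remains, tr(S S^T) = ||S||_F^2
  expect_equal(bhm_objective(S, I6, S, lam), lam * sum(S^2), tolerance = 1e-10)
  # W = 0: only the data term remains
  expect_equal(bhm_objective(matrix(0, 6, 6), I6, S, lam), sum(S^2),
               tolerance = 1e-10)
})

test_that("objective rejects indefinite Omega", {
  S <- rand_sym(4, seed = 1)
  Bad <- diag(c(1, 1, 1, -1))
  expect_error(bhm_objective(S, Bad, S, 0.1), "positive definite")
})

test_that("one unstabilised Omega update from identity is the raw CC matrix", {
  W <- rand_sym(6, seed = 8)
  out <- update_omega(W, diag(6), delta = 0, inner_iters = 1)
  expect_equal(max(abs(out - t(W) %*% W)), 0)
})

test_that("Omega update has the expected closed form for identity W", {
  out <- update_omega(diag(4), diag(4), delta = 0.1, inner_iters = 1)
  expect_equal(out, 1.1 * diag(4), tolerance = 1e-14)
})

test_that("repeated Omega updates match explicit sequential evaluation", {
  W <- rand_sym(6, seed = 15)
  Om0 <- rand_spd(6, seed = 16)
  delta <- 0.1
  # oracle: two explicit applications with a dense solve()
  Om1 <- t(W) %*% solve(Om0) %*% W + delta * diag(6)
  Om2 <- t(W) %*% solve(Om1) %*% W + delta * diag(6)
  out <- update_omega(W, Om0, delta = delta, inner_iters = 2)
  expect_lt(max(abs(out - Om2)), 1e-10)
})

test_that("Omega update refuses a singular start", {
  W <- rand_sym(4, seed = 2)
  expect_error(update_omega(W, matrix(0, 4, 4), delta = 0.1), "positive definite")
})

test_that("closed-form W update solves its stationarity equation", {
  for (seed in 1:10) {
    p <- 6
    S <- rand_sym(p, seed)
    Omega <- rand_spd(p, seed + 50)
    lam <- 0.5
    W <- update_w(S, Omega, lam)
    Oi <- solve(Omega)
    resid <- W + lam * Oi %*% W %*% Oi - S
    expect_lt(max(abs(resid)), 1e-10)
    expect_lt(fd_gradient_norm(S, Omega, lam, W), 1e-6)
    expect_lt(max(abs(W - t(W))), 1e-12)
  }
})

test_that("W update reduces to shrinkage for identity Omega and to S for tiny lam", {
  S <- rand_sym(7, seed = 33)
  lam <- 0.4
  expect_equal(update_w(S, diag(7), lam), S / (1 + lam), tolerance = 1e-12)
  expect_equal(update_w(S, rand_spd(7, 5), 1e-12), S, tolerance = 1e-9)
})

test_that("W update rejects non-positive Omega eigenvalues", {
  S <- rand_sym(4, seed = 4)
  expect_error(update_w(S, diag(c(2, 1, 0, 1)), 0.1), "eigenvalue")
})

test_that("the alternation converges with a non-increasing objective", {
  for (lam in c(1e-4, 1e-2)) {
    for (seed in 1:3) {
      X <- rand_ts(50, 20, seed = seed)
      fit <- fit_bhm(X, bhm_config(lam = lam))
      expect_true(fit$converged)
      expect_lte(max(diff(fit$objective_trace)), 1e-8)
      Om <- as.matrix(fit$Omega)
      expect_lt(max(abs(Om - t(Om))), 1e-10)
      expect_gt(min(eigen(Om, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  }
})

test_that("vanishing regularisation recovers the correlation network", {
  X <- rand_ts(50, 20, seed = 7)
  fit <- fit_bhm(X, bhm_config(lam = 1e-8))
  W_pc <- as.matrix(pc_network(X))
  expect_lt(max(abs(as.matrix(fit$W) - W_pc)), 1e-6)
  expect_lt(fnorm_test(as.matrix(fit$W) - W_pc) / fnorm_test(W_pc), 1e-4)
})

test_that("first high-order iterate agrees with correlation's correlation", {
  # the two differ only by the column centring/normalisation of the second
  # correlation pass, a 1/p-order correction, so atlas-like widths are used
  for (seed in 1:5) {
    X <- rand_ts(175, 80, seed = seed)
    W <- as.matrix(pc_network(X))
    Om1 <- update_omega(W, diag(80), delta = 0, inner_iters = 1)
    H <- as.matrix(cc_network(W))
    ut <- upper.tri(Om1)
    expect_gt(cor(Om1[ut], H[ut]), 0.99)
  }
})

test_that("single-application updates abort on a diverging objective", {
  X <- rand_ts(50, 20, seed = 9)
  cfg <- bhm_config(lam = 0.1, omega_inner_iters = 1)
  expect_error(fit_bhm(X, cfg), "diverging")
})

test_that("estimated Omega recovers a planted two-block structure", {
  p <- 10
  blocks <- rep(1:2, each = 5)
  hits <- 0
  for (seed in 1:10) {
    spec <- synthetic_spec(p = p, n = 175, n_per_group = 1,
                           block_sizes = c(5, 5), within_block_corr = 0.6,
                           effect_edges = 1, effect_size = 0, seed = seed)
    coh <- simulate_cohort(spec)
    fit <- fit_bhm(coh$subjects[[1]], bhm_config(lam = 0.01))
    Om <- as.matrix(fit$Omega)
    same <- outer(blocks, blocks, "==") & upper.tri(Om)
    diff_blk <- outer(blocks, blocks, "!=") & upper.tri(Om)
    if (mean(Om[same]) > mean(Om[diff_blk])) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
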