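test_that("pc_network matches the per-pair correlation definition", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(6:30, 1)
    p <- sample(3:10, 1)
    X <- matrix(rnorm(n * p), n, p)
    W <- pc_network(X)
    expect_lt(max(abs(as.matrix(W) - pairwise_pc_matrix(X))), 1e-12)
  }
})

test_that("pc_network flags perfect and anti-perfect correlation", {
  x <- rnorm(12)
  X <- cbind(x, x, -x) + 0   # duplicated and negated signals
  W <- pc_network(X)
  expect_equal(W[1, 2], 1)
  expect_equal(W[1, 3], -1)
  expect_equal(unname(diag(as.matrix(W))), rep(1, 3))
  expect_true(all(abs(W) <= 1))
})

test_that("shrunk correlations equal pc / (1 + lam) across a lambda grid", {
  X <- rand_ts(40, 8, seed = 3)
  W <- as.matrix(pc_network(X))
  for (lam in c(0, 1e-3, 0.5, 1, 3, 10)) {
    expect_equal(as.matrix(shrunk_pc_network(X, lam)), W / (1 + lam),
                 tolerance = 0)
  }
  # lam = 0 is the plain correlation network, exactly
  expect_identical(as.matrix(shrunk_pc_network(X, 0)), W)
  # lam = 3 turns a correlation of 0.8 into 0.2
  expect_equal(0.8 / (1 + 3), 0.2)
  expect_error(shrunk_pc_network(X, -0.1), "nonnegative")
})

test_that("sparse representation zeroes out under a dominating penalty", {
  X <- rand_ts(20, 5, seed = 7)
  S <- crossprod(normalize_signals(X))
  lam_big <- 2 * max(abs(S[upper.tri(S)]))
  W <- sr_network(X, lam_big + 0.01)
  expect_true(all(as.matrix(W) == 0))
})

test_that("sparse representation keeps an exactly zero diagonal", {
  for (seed in c(1, 9)) {
    W <- sr_network(rand_ts(25, 6, seed = seed), lam = 0.2)
    expect_identical(diag(as.matrix(W)), rep(0, 6))
  }
})

test_that("sparse representation matches coordinate-wise grid search", {
  # both routes are run to tight convergence: with only 5 time points the
  # ROI signals are strongly collinear and coordinate updates contract slowly
  X <- rand_ts(5, 3, seed = 13)
  lam <- 0.1
  W <- as.matrix(sr_network(X, lam, tol = 1e-12, max_sweeps = 1e5))
  Xn <- normalize_signals(X)
  for (i in 1:3) {
    w_oracle <- lasso_column_grid(Xn, i, lam, sweeps = 500, tol = 1e-11)
    expect_lt(max(abs(W[-i, i] - w_oracle)), 1e-6)
  }
})

test_that("sparse representation solution is a local minimum", {
  X <- rand_ts(30, 5, seed = 21)
  lam <- 0.3
  Xn <- normalize_signals(X)
  W <- as.matrix(sr_network(X, lam))
  objective <- function(M) {
    sum((Xn - Xn %*% M)^2) + lam * sum(abs(M))
  }
  obj_hat <- objective(W)
  expect_lte(obj_hat, objective(matrix(0, 5, 5)))
  set.seed(99)
  for (k in 1:1000) {
    P <- matrix(rnorm(25, sd = 1e-3), 5, 5)
    diag(P) <- 0   # perturbations respect the zero-diagonal constraint
    expect_lte(obj_hat, objective(W + P) + 1e-12)
  }
})

test_that("sparse representation agrees with an independent lasso solver", {
  X <- rand_ts(40, 6, seed = 31)
  Xn <- normalize_signals(X)
  lam <- 0.25
  W <- as.matrix(sr_network(X, lam))
  n <- nrow(Xn)
  for (i in c(1, 4)) {
    fit <- glmnet::glmnet(Xn[, -i], Xn[, i], lambda = lam / (2 * n),
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-14)
    expect_lt(max(abs(W[-i, i] - as.numeric(fit$beta))), 1e-6)
  }
})

test_that("correlation's correlation equals column-wise correlation of W", {
  W <- as.matrix(pc_network(rand_ts(30, 8, seed = 17)))
  H <- cc_network(W)
  # independent oracle: per-pair correlation of the connectivity profiles
  expect_lt(max(abs(as.matrix(H) - pairwise_pc_matrix(W))), 1e-12)
  expect_equal(diag(as.matrix(H)), rep(1, 8))
})

test_that("identical connectivity profiles are maximally high-order connected", {
  W <- matrix(rnorm(16), 4, 4)
  W[, 2] <- W[, 1]
  H <- cc_network(W)
  expect_equal(H[1, 2], 1)
})

test_that("cc of a pc network is a valid correlation matrix", {
  for (seed in 1:5) {
    H <- as.matrix(cc_network(pc_network(rand_ts(40, 7, seed = seed))))
    expect_lt(max(abs(H - t(H))), 1e-12)
    expect_equal(diag(H), rep(1, 7))
    expect_gt(min(eigen(H, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
})

test_that("cc rejects constant connectivity profiles", {
  W <- matrix(rnorm(16), 4, 4)
  W[, 3] <- 2
  expect_error(cc_network(W), "column\\(s\\) 3")
})

test_that("soft thresholding shrinks, zeroes and mirrors correlations", {
  # scalar behaviour via a two-ROI construction is clearer as direct checks
  st <- function(s, lam) sign(s) * pmax(abs(s) - lam, 0)
  expect_equal(st(0.7, 0.2), 0.5)
  expect_equal(st(0.1, 0.2), 0)
  expect_equal(st(-0.7, 0.2), -0.5)
  X <- rand_ts(30, 6, seed = 23)
  W <- as.matrix(pc_network(X))
  expect_equal(as.matrix(soft_threshold_network(X, 0.2)), st(W, 0.2),
               tolerance = 0)
  expect_identical(as.matrix(soft_threshold_network(X, 0)), W)
  expect_error(soft_threshold_network(X, -1), "nonnegative")
})

test_that("soft thresholding minimises the per-edge Laplacian-prior objective", {
  # grid-search argmin of 0.5 w^2 - s w + lam |w| over a 1e-4 grid
  set.seed(41)
  grid <- seq(-1.5, 1.5, by = 1e-4)
  for (k in 1:100) {
    s <- runif(1, -1, 1)
    lam <- runif(1, 0, 0.8)
    vals <- 0.5 * grid^2 - s * grid + lam * abs(grid)
    w_grid <- grid[which.min(vals)]
    w_hat <- sign(s) * max(abs(s) - lam, 0)
    expect_lt(abs(w_hat - w_grid), 1e-4 + 1e-12)
  }
})
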