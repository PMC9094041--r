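# Independent oracles and fixture builders used across the test files.
# Everything here deliberately avoids the package's own computational
# shortcuts: correlations are computed per pair from the raw definition,
# lasso solutions by grid search, gradients by finite differences.

fnorm_test <- function(M) sqrt(sum(M^2))

rand_ts <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}

rand_spd <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p, p)
  crossprod(A) / p + 0.5 * diag(p)
}

rand_sym <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p, p)
  (A + t(A)) / 2
}

# Sample Pearson correlation of two vectors straight from its definition.
pairwise_pc <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

pairwise_pc_matrix <- function(X) {
  p <- ncol(X)
  M <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      M[i, j] <- M[j, i] <- pairwise_pc(X[, i], X[, j])
    }
  }
  M
}

# L1-regularised representation of column i of a normalised matrix, solved
# by cyclic coordinate-wise grid search with three refinement levels (no
# closed-form update anywhere).
lasso_column_grid <- function(Xn, i, lam, sweeps = 100, tol = 1e-9) {
  others <- Xn[, -i, drop = FALSE]
  y <- Xn[, i]
  objfun <- function(w) sum((y - others %*% w)^2) + lam * sum(abs(w))
  w <- numeric(ncol(others))
  for (s in seq_len(sweeps)) {
    w_old <- w
    for (k in seq_along(w)) {
      centre <- w[k]
      width <- 1.5
      for (lvl in 1:3) {
        grid <- seq(centre - width, centre + width, length.out = 2001)
        vals <- vapply(grid, function(g) {
          w2 <- w; w2[k] <- g; objfun(w2)
        }, numeric(1))
        centre <- grid[which.min(vals)]
        width <- width / 500
      }
      w[k] <- centre
    }
    if (max(abs(w - w_old)) < tol) break
  }
  w
}

# Finite-difference gradient (central differences) of the low-order
# subproblem objective g(W) = ||W - S||_F^2 + lam tr(Oi W Oi t(W)).
fd_gradient_norm <- function(S, Omega, lam, W, h = 1e-5) {
  Oi <- solve(Omega)
  g <- function(W) sum((W - S)^2) + lam * sum(diag(Oi %*% W %*% Oi %*% t(W)))
  p <- nrow(W)
  G <- matrix(0, p, p)
  for (a in seq_len(p)) {
    for (b in seq_len(p)) {
      E <- matrix(0, p, p)
      E[a, b] <- h
      G[a, b] <- (g(W + E) - g(W - E)) / (2 * h)
    }
  }
  sqrt(sum(G^2))
}

# Small ready-made cohorts for pipeline tests.
small_planted_cohort <- function(seed = 11) {
  simulate_cohort(synthetic_spec(p = 10, n = 175, n_per_group = 10,
                                 within_block_corr = 0.3,
                                 effect_edges = 10, effect_size = 0.6,
                                 seed = seed))
}

small_null_cohort <- function(seed = 5) {
  simulate_cohort(synthetic_spec(p = 10, n = 100, n_per_group = 10,
                                 effect_edges = 1, effect_size = 0,
                                 seed = seed))
}
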