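#' Pearson-correlation network
#'
#' The canonical low-order brain functional network: entry (i, j) is the
#' sample Pearson correlation of the signals of ROIs i and j. After
#' column normalisation (centre + unit norm) this is simply `t(X) %*% X`.
#'
#' @param X time-series matrix (normalised internally if needed).
#' @return `bfn` with unit diagonal and off-diagonals in `[-1, 1]`.
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' pc_network(X)
#' @export
pc_network <- function(X) {
  Xn <- normalize_signals(X)
  W <- sym(crossprod(Xn))
  W[] <- pmin(pmax(W, -1), 1)
  diag(W) <- 1
  new_bfn(W, "low", "pc", colnames(Xn))
}

#' Shrunk Pearson-correlation network
#'
#' Ridge-regularised variant of [pc_network()]: a zero-mean Gaussian prior on
#' each edge weight shrinks every correlation by the factor `1 / (1 + lam)`.
#' `lam = 0` reproduces the plain correlation network exactly.
#'
#' @param X time-series matrix.
#' @param lam nonnegative shrinkage hyper-parameter.
#' @return `bfn` equal to `pc_network(X) / (1 + lam)`.
#' @export
shrunk_pc_network <- function(X, lam) {
  if (!is.numeric(lam) || length(lam) != 1 || !is.finite(lam) || lam < 0) {
    stop("lam must be a single nonnegative number", call. = FALSE)
  }
  W <- pc_network(X)
  vals <- as.matrix(W) / (1 + lam)
  new_bfn(vals, "low", "shrunk-pc", colnames(vals))
}

#' Sparse-representation network
#'
#' Partial-correlation-style network: each ROI signal is regressed on all
#' other ROI signals under an L1 penalty,
#' `min_w ||x_i - sum_{j != i} w_ij x_j||^2 + lam * sum_{j != i} |w_ij|`,
#' with the self-weight constrained to zero. Column i of the result holds the
#' regression coefficients for ROI i. The solution is generally asymmetric;
#' the classification pipeline symmetrises it by `(W + t(W)) / 2`.
#'
#' Solved by cyclic coordinate descent on the normalised Gram matrix.
#'
#' @param X time-series matrix.
#' @param lam positive L1 penalty.
#' @param max_sweeps cap on full coordinate sweeps per column.
#' @param tol convergence threshold on the largest coefficient change.
#' @return `bfn` with an exactly zero diagonal.
#' @export
sr_network <- function(X, lam, max_sweeps = 10000, tol = 1e-8) {
  if (!is.numeric(lam) || length(lam) != 1 || !is.finite(lam) || lam <= 0) {
    stop("lam must be a single positive number", call. = FALSE)
  }
  Xn <- normalize_signals(X)
  S <- crossprod(Xn)
  p <- ncol(S)
  W <- matrix(0, p, p)
  for (i in seq_len(p)) {
    w <- numeric(p)           # slot i stays clamped at zero
    others <- seq_len(p)[-i]
    delta <- Inf
    for (sweep_k in seq_len(max_sweeps)) {
      delta <- 0
      for (j in others) {
        # partial residual correlation of x_j after removing other terms
        r <- S[j, i] - sum(w * S[, j]) + w[j] * S[j, j]
        wj <- soft_threshold(r, lam / 2) / S[j, j]
        delta <- max(delta, abs(wj - w[j]))
        w[j] <- wj
      }
      if (delta < tol) break
    }
    if (delta >= tol) {
      stop("coordinate descent did not converge for ROI column ", i,
           " after ", max_sweeps, " sweeps", call. = FALSE)
    }
    W[, i] <- w
  }
  new_bfn(W, "low", "sr", colnames(Xn))
}

# L1-regularised representation objective of a single column; used by
# sr_network tests and by the local-optimality checks.
sr_column_objective <- function(S, i, w, lam) {
  idx <- seq_len(nrow(S))[-i]
  wi <- numeric(nrow(S))
  wi[idx] <- w
  S[i, i] - 2 * sum(wi * S[, i]) + drop(crossprod(wi, S %*% wi)) +
    lam * sum(abs(wi))
}

#' Correlation's-correlation network
#'
#' High-order network obtained by a second correlation pass: the columns of a
#' low-order network (the connectivity profiles of the ROIs) are centred and
#' unit-normalised, and their cross-product is returned. Two ROIs are thereby
#' connected when their connection *patterns* agree, regardless of the
#' strength of their direct signal correlation. The full columns, including
#' the diagonal entries, enter the second correlation.
#'
#' @param W square low-order network (typically a [pc_network()] output).
#' @return `bfn` with `order_tag = "high"`, unit diagonal, entries in
#'   `[-1, 1]`.
#' @export
cc_network <- function(W) {
  W <- as.matrix(W)
  if (!is.matrix(W) || nrow(W) != ncol(W)) {
    stop("cc_network expects a square network matrix", call. = FALSE)
  }
  ctr <- sweep(W, 2, colMeans(W), "-")
  nrm <- sqrt(colSums(ctr^2))
  flat <- which(nrm == 0)
  if (length(flat)) {
    stop("constant connectivity profile (zero variance) in column(s) ",
         paste(flat, collapse = ", "), call. = FALSE)
  }
  Wn <- sweep(ctr, 2, nrm, "/")
  H <- sym(crossprod(Wn))
  H[] <- pmin(pmax(H, -1), 1)
  diag(H) <- 1
  new_bfn(H, "high", "cc", colnames(W))
}

#' Soft-thresholded correlation network
#'
#' Sparse low-order network from a Laplacian (double-exponential) prior on
#' each edge weight: the closed-form estimate is entrywise two-sided soft
#' thresholding of the correlation matrix,
#' `sign(s) * max(|s| - lam, 0)` for `s = t(x_i) %*% x_j`.
#' Correlations weaker than `lam` in magnitude are zeroed; stronger ones are
#' shrunk toward zero by `lam`. `lam = 0` reproduces [pc_network()].
#'
#' @param X time-series matrix.
#' @param lam nonnegative threshold.
#' @return `bfn` with `estimator_tag = "soft-threshold"`.
#' @export
soft_threshold_network <- function(X, lam) {
  if (!is.numeric(lam) || length(lam) != 1 || !is.finite(lam) || lam < 0) {
    stop("lam must be a single nonnegative number", call. = FALSE)
  }
  W <- as.matrix(pc_network(X))
  vals <- soft_threshold(W, lam)
  new_bfn(vals, "low", "soft-threshold", colnames(W))
}
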