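#' Configuration for the Bayesian high-order model
#'
#' @param lam positive balance hyper-parameter weighting the matrix-normal
#'   prior against the data-fidelity term. Small values (1e-4 .. 1e-2) keep
#'   the low-order network close to the plain correlation matrix; large
#'   values let the high-order structure reshape it.
#' @param delta positive ridge added to every high-order update
#'   (`Omega <- t(W) Omega^-1 W + delta * I`) to keep `Omega` positive
#'   definite and to damp the update map; default 0.1.
#' @param max_outer_iters cap on outer alternating iterations (default 100).
#' @param tol outer convergence threshold on the larger of the relative
#'   Frobenius changes of `W` and `Omega` (default 1e-5).
#' @param omega_inner_iters cap on applications of the `Omega` update map
#'   within one outer step (default 500). The inner loop stops early once the
#'   map has reached its fixed point (relative change below
#'   `omega_inner_tol`); setting `omega_inner_iters = 1` applies the map once
#'   per outer step, which reproduces the classical
#'   correlation's-correlation matrix at the first iteration but makes the
#'   alternation oscillate (see the methods vignette).
#' @param omega_inner_tol early-stopping tolerance of the inner loop
#'   (default 1e-9).
#' @return a `bhm_config` list.
#' @export
bhm_config <- function(lam, delta = 0.1, max_outer_iters = 100, tol = 1e-5,
                       omega_inner_iters = 500, omega_inner_tol = 1e-9) {
  if (!is.numeric(lam) || length(lam) != 1 || !is.finite(lam) || lam <= 0) {
    stop("lam must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0) {
    stop("delta must be a single positive number", call. = FALSE)
  }
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  if (max_outer_iters < 1 || omega_inner_iters < 1) {
    stop("iteration caps must be positive integers", call. = FALSE)
  }
  structure(list(lam = lam, delta = delta,
                 max_outer_iters = as.integer(max_outer_iters), tol = tol,
                 omega_inner_iters = as.integer(omega_inner_iters),
                 omega_inner_tol = omega_inner_tol),
            class = "bhm_config")
}

#' Joint objective of the Bayesian high-order model
#'
#' Evaluates
#' `||W - S||_F^2 + lam * (tr(Omega^-1 W Omega^-1 t(W)) + p * log det(Omega))`
#' where `S` is the correlation matrix the low-order network is anchored to.
#' The trace + log-determinant pair is the negative log of the matrix-variate
#' normal prior on `W` with shared row/column covariance `Omega` (additive
#' constants dropped; the prior's 1/2 is absorbed into `lam`).
#'
#' @param W low-order network iterate (`p x p`).
#' @param Omega symmetric positive definite high-order network (`p x p`).
#' @param S anchor correlation matrix (`p x p`).
#' @param lam positive balance hyper-parameter.
#' @return a finite scalar.
#' @export
bhm_objective <- function(W, Omega, S, lam) {
  W <- as.matrix(W); Omega <- as.matrix(Omega); S <- as.matrix(S)
  p <- nrow(S)
  stopifnot(all(dim(W) == p), all(dim(Omega) == p), lam > 0)
  Oi <- inv_spd(Omega, "Omega iterate")
  ld <- log_det_spd(Omega, "Omega iterate")
  OiW <- Oi %*% W
  prior_tr <- sum(OiW * (W %*% Oi))   # tr(Oi W Oi t(W)) = sum(Oi W * W Oi)
  val <- sum((W - S)^2) + lam * (prior_tr + p * ld)
  if (!is.finite(val)) stop("objective is not finite", call. = FALSE)
  val
}

#' High-order network update (Step 1 of the alternation)
#'
#' Applies the fixed-point map `Omega <- t(W) %*% solve(Omega) %*% W +
#' delta * I` for `inner_iters` iterations starting from `Omega_prev`,
#' optionally stopping early once the map has converged. With
#' `Omega_prev = I`, `delta = 0` and a single application the result is
#' exactly `t(W) %*% W` — the (unnormalised) correlation's-correlation
#' matrix, which is thus the first iterate of the model's high-order network.
#'
#' @param W low-order network (`p x p`).
#' @param Omega_prev symmetric positive definite starting value.
#' @param delta nonnegative stabilising ridge added at every application.
#' @param inner_iters number of applications of the map.
#' @param inner_tol early-stopping threshold on the relative Frobenius
#'   change between applications; the default 0 disables early stopping so
#'   that exactly `inner_iters` applications are performed.
#' @return symmetric matrix; positive definite whenever `delta > 0`.
#' @export
update_omega <- function(W, Omega_prev, delta, inner_iters = 1,
                         inner_tol = 0) {
  W <- as.matrix(W); Omega <- as.matrix(Omega_prev)
  p <- nrow(W)
  stopifnot(all(dim(Omega) == p), delta >= 0, inner_iters >= 1)
  Imat <- diag(p)
  for (k in seq_len(inner_iters)) {
    Oi <- inv_spd(Omega, "Omega_prev")
    Om_new <- t(W) %*% Oi %*% W + delta * Imat
    Om_new <- sym(Om_new)
    if (inner_tol > 0 && fnorm(Om_new - Omega) <= inner_tol * fnorm(Omega)) {
      Omega <- Om_new
      break
    }
    Omega <- Om_new
  }
  Omega
}

#' Low-order network update (Step 2 of the alternation)
#'
#' Closed-form solution of the quadratic subproblem
#' `min_W ||W - S||_F^2 + lam * tr(Omega^-1 W Omega^-1 t(W))`, i.e. the
#' unique `W` with `W + lam * Omega^-1 W Omega^-1 = S`. In the eigenbasis
#' `Omega = U diag(L) t(U)` the solution filters each coordinate of `S`:
#' `Wt[a, b] = St[a, b] / (1 + lam / (L[a] * L[b]))`. With `Omega = I` this
#' is the shrunk correlation network `S / (1 + lam)`; as `lam -> 0` it tends
#' to `S` itself.
#'
#' @param S symmetric anchor matrix (`p x p`).
#' @param Omega symmetric positive definite matrix (`p x p`).
#' @param lam positive balance hyper-parameter.
#' @return symmetric matrix solving the stationarity equation.
#' @export
update_w <- function(S, Omega, lam) {
  S <- as.matrix(S); Omega <- as.matrix(Omega)
  stopifnot(lam > 0)
  e <- eigen(sym(Omega), symmetric = TRUE)
  if (any(e$values <= 0)) {
    stop("Omega has a non-positive eigenvalue (",
         format(min(e$values)), "); cannot solve the W subproblem",
         call. = FALSE)
  }
  U <- e$vectors
  L <- e$values
  St <- crossprod(U, S) %*% U
  Wt <- St / (1 + lam / outer(L, L))
  sym(U %*% Wt %*% t(U))
}

#' Fit the Bayesian high-order model
#'
#' Jointly estimates a subject's low-order network `W` and high-order
#' network `Omega` by alternating optimisation of the penalised objective
#' (see [bhm_objective()]): starting from `W = t(X) %*% X` (the correlation
#' network) and `Omega = I`, each outer iteration first drives the
#' high-order update map to its fixed point ([update_omega()]) and then
#' solves the low-order subproblem in closed form ([update_w()]). Iteration
#' stops when both matrices change by less than `config$tol` in relative
#' Frobenius norm, or at `config$max_outer_iters`.
#'
#' The objective is checked every iteration; an increase beyond 1e-6
#' relative aborts with an error, which typically indicates a `lam` too
#' large for a stable alternation.
#'
#' @param X time-series matrix (normalised internally).
#' @param config a [bhm_config()].
#' @param verbose emit one message per outer iteration (iteration number,
#'   objective, relative changes of `W` and `Omega`).
#' @return `bhm_fit` list: `W` (`bfn`, low order), `Omega` (`bfn`, high
#'   order, symmetric positive definite), `objective_trace`, `n_iters`,
#'   `converged`, `config`.
#' @examples
#' X <- matrix(rnorm(50 * 8), 50, 8)
#' fit <- fit_bhm(X, bhm_config(lam = 0.01))
#' fit$converged
#' @export
fit_bhm <- function(X, config, verbose = FALSE) {
  if (!inherits(config, "bhm_config")) {
    stop("config must be created with bhm_config()", call. = FALSE)
  }
  Xn <- normalize_signals(X)
  p <- ncol(Xn)
  S <- sym(crossprod(Xn))
  W <- S
  Omega <- diag(p)
  trace <- numeric(0)
  converged <- FALSE
  n_iters <- 0L
  for (k in seq_len(config$max_outer_iters)) {
    Omega_new <- update_omega(W, Omega, config$delta,
                              inner_iters = config$omega_inner_iters,
                              inner_tol = config$omega_inner_tol)
    W_new <- update_w(S, Omega_new, config$lam)
    dW <- fnorm(W_new - W) / fnorm(W)
    dO <- fnorm(Omega_new - Omega) / fnorm(Omega)
    W <- W_new
    Omega <- Omega_new
    J <- bhm_objective(W, Omega, S, config$lam)
    if (length(trace) && J > trace[length(trace)] + 1e-6 * abs(trace[length(trace)])) {
      stop(sprintf(paste0(
        "objective increased at outer iteration %d (%.6g -> %.6g): ",
        "the alternation is diverging; lam = %g is likely too large for a ",
        "stable fit"), k, trace[length(trace)], J, config$lam), call. = FALSE)
    }
    trace <- c(trace, J)
    n_iters <- k
    if (verbose) {
      message(sprintf("iter=%d J=%.8g dW=%.3e dOmega=%.3e", k, J, dW, dO))
    }
    if (max(dW, dO) < config$tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(
    W = new_bfn(W, "low", "bhm-w", colnames(Xn)),
    Omega = new_bfn(Omega, "high", "bhm-omega", colnames(Xn)),
    objective_trace = trace,
    n_iters = n_iters,
    converged = converged,
    config = config
  ), class = "bhm_fit")
}

#' @export
print.bhm_fit <- function(x, ...) {
  cat(sprintf("<bhm_fit> p = %d ROIs, lam = %g, delta = %g\n",
              nrow(x$W), x$config$lam, x$config$delta))
  cat(sprintf("  %s after %d outer iterations, final objective %.6g\n",
              if (x$converged) "converged" else "stopped (iteration cap)",
              x$n_iters, x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}
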