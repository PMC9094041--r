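#' Specification of a synthetic rs-fMRI cohort
#'
#' Describes a two-group cohort whose statistical structure matches the
#' assumptions of the estimators in this package: each subject's ROI signals
#' are i.i.d. multivariate-normal time points drawn from a subject-specific
#' correlation matrix, which is itself a matrix-normal perturbation of a
#' block-structured group template. Group 1 additionally has `effect_size`
#' added to `effect_edges` randomly chosen between-block (zero-template)
#' edges; those edges are the planted group-discriminative ground truth.
#'
#' Defaults mirror a typical single-site rs-fMRI study at test scale:
#' 175 time points per subject and 40 subjects per group, with 20 ROIs
#' instead of a full atlas so that whole-cohort simulations stay cheap.
#'
#' @param p number of ROIs (default 20).
#' @param n time points per subject (default 175).
#' @param n_per_group subjects per group (default 40).
#' @param block_sizes sizes of the diagonal correlation blocks; must sum to
#'   `p` (default: two equal halves).
#' @param within_block_corr template correlation inside a block, in `[0, 1)`
#'   (default 0.5).
#' @param effect_edges number of planted discriminative edges (default 10).
#' @param effect_size correlation shift added on planted edges (default 0.3).
#' @param subject_sd scale of the matrix-normal subject-level perturbation
#'   of the template (default 0.05).
#' @param seed integer RNG seed; the cohort is a pure function of the spec.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(p = 20, n = 175, n_per_group = 40,
                           block_sizes = NULL, within_block_corr = 0.5,
                           effect_edges = 10, effect_size = 0.3,
                           subject_sd = 0.05, seed = 1) {
  block_sizes <- block_sizes %||% c(ceiling(p / 2), floor(p / 2))
  if (sum(block_sizes) != p) {
    stop("block_sizes must sum to p (", p, "), got ", sum(block_sizes),
         call. = FALSE)
  }
  if (p < 2 || n < 2 || n_per_group < 1) {
    stop("need p >= 2, n >= 2, n_per_group >= 1", call. = FALSE)
  }
  if (within_block_corr < 0 || within_block_corr >= 1) {
    stop("within_block_corr must lie in [0, 1)", call. = FALSE)
  }
  if (effect_edges > p * (p - 1) / 2) {
    stop("effect_edges exceeds the number of available edges", call. = FALSE)
  }
  if (abs(within_block_corr) + abs(effect_size) >= 1) {
    stop("within_block_corr + effect_size must keep correlations in (-1, 1)",
         call. = FALSE)
  }
  if (subject_sd < 0) stop("subject_sd must be nonnegative", call. = FALSE)
  structure(list(p = as.integer(p), n = as.integer(n),
                 n_per_group = as.integer(n_per_group),
                 block_sizes = as.integer(block_sizes),
                 within_block_corr = within_block_corr,
                 effect_edges = as.integer(effect_edges),
                 effect_size = effect_size, subject_sd = subject_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Block-diagonal group correlation template
#'
#' Compound-symmetry blocks: 1 on the diagonal, `within_block_corr` inside
#' each block, 0 between blocks. Positive definiteness is checked (the
#' smallest eigenvalue of a compound-symmetry block of size b and
#' correlation r is `1 - r`, so any `r` in `[0, 1)` passes).
#'
#' @param spec a [synthetic_spec()].
#' @return `bfn` (low order, tag `"template"`).
#' @export
make_group_template <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- spec$p
  M <- matrix(0, p, p)
  at <- 0
  for (b in spec$block_sizes) {
    idx <- at + seq_len(b)
    M[idx, idx] <- spec$within_block_corr
    at <- at + b
  }
  diag(M) <- 1
  if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("template is not positive definite; lower within_block_corr",
         call. = FALSE)
  }
  new_bfn(M, "low", "template")
}

# One matrix-variate normal draw E = L Z t(L) with row and column covariance
# Omega = L t(L); vec(E) has covariance Omega (x) Omega.
rmatnorm_sym <- function(Omega) {
  p <- nrow(Omega)
  L <- t(chol(Omega))
  Z <- matrix(stats::rnorm(p * p), p, p)
  L %*% Z %*% t(L)
}

# Project a symmetric matrix to a positive definite matrix with unit
# diagonal: clip eigenvalues at `eps`, rescale to unit diagonal, repeat.
pd_project <- function(M, eps = 1e-6, max_steps = 100) {
  for (k in seq_len(max_steps)) {
    M <- sym(M)
    e <- eigen(M, symmetric = TRUE)
    if (min(e$values) >= eps && max(abs(diag(M) - 1)) < 1e-12) return(M)
    vals <- pmax(e$values, eps)
    M <- e$vectors %*% (vals * t(e$vectors))
    d <- sqrt(diag(M))
    M <- M / tcrossprod(d)
    diag(M) <- 1
  }
  stop("positive-definite projection did not converge in ", max_steps,
       " steps", call. = FALSE)
}

sample_subject_network_impl <- function(template, Omega_true, scale) {
  template <- as.matrix(template)
  if (scale == 0) return(template)
  E <- rmatnorm_sym(as.matrix(Omega_true))
  pd_project(template + scale * sym(E))
}

#' Draw one subject-level correlation matrix
#'
#' Perturbs the group template by a symmetrised matrix-variate normal draw
#' with row/column covariance `Omega_true` and projects the result back to a
#' positive definite matrix with unit diagonal. `scale = 0` returns the
#' template unchanged.
#'
#' @param template group correlation template (`p x p`).
#' @param Omega_true symmetric positive definite covariance of the
#'   perturbation.
#' @param scale nonnegative perturbation magnitude.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return symmetric positive definite matrix with unit diagonal.
#' @export
sample_subject_network <- function(template, Omega_true, scale, seed) {
  with_seed(seed, sample_subject_network_impl(template, Omega_true, scale))
}

#' Simulate a two-group cohort
#'
#' Fully reproducible from `spec$seed`. Group 0 subjects are drawn around
#' the block template; group 1 subjects around the template with
#' `effect_size` added on `effect_edges` randomly chosen between-block
#' edges. Each subject contributes `n` i.i.d. multivariate-normal time
#' points with the subject's correlation matrix as covariance.
#'
#' @param spec a [synthetic_spec()].
#' @return a `cohort` list: `subjects` (list of time-series matrices),
#'   `labels` (0/1 vector, group 1 = positive class), `truth_edges`
#'   (two-column matrix of planted (i, j) pairs, i < j), `truth_omega`
#'   (the block template used as perturbation covariance), `spec`.
#' @examples
#' coh <- simulate_cohort(synthetic_spec(p = 6, n = 40, n_per_group = 3))
#' length(coh$subjects); coh$labels
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    tmpl0 <- as.matrix(make_group_template(spec))
    p <- spec$p
    ei <- edge_index(p)
    off_block <- ei[tmpl0[ei] == 0, , drop = FALSE]
    if (nrow(off_block) < spec$effect_edges) {
      stop("not enough between-block edges (", nrow(off_block),
           ") to plant ", spec$effect_edges, " effects", call. = FALSE)
    }
    picked <- sort(sample.int(nrow(off_block), spec$effect_edges))
    truth_edges <- off_block[picked, , drop = FALSE]
    tmpl1 <- tmpl0
    for (r in seq_len(nrow(truth_edges))) {
      i <- truth_edges[r, 1]; j <- truth_edges[r, 2]
      tmpl1[i, j] <- tmpl1[j, i] <- tmpl1[i, j] + spec$effect_size
    }
    tmpl1 <- pd_project(tmpl1)
    n_sub <- 2L * spec$n_per_group
    labels <- rep(c(0L, 1L), each = spec$n_per_group)
    subjects <- vector("list", n_sub)
    for (s in seq_len(n_sub)) {
      tmpl <- if (labels[s] == 0L) tmpl0 else tmpl1
      Csub <- sample_subject_network_impl(tmpl, tmpl0, spec$subject_sd)
      subjects[[s]] <- matrix(stats::rnorm(spec$n * p), spec$n, p) %*% chol(Csub)
    }
    structure(list(subjects = subjects, labels = labels,
                   truth_edges = truth_edges, truth_omega = tmpl0,
                   spec = spec),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d / %d per group), p = %d ROIs, n = %d time points\n",
              length(x$subjects), sum(x$labels == 0), sum(x$labels == 1),
              ncol(x$subjects[[1]]), nrow(x$subjects[[1]])))
  if (!is.null(x$truth_edges)) {
    cat(sprintf("  %d planted discriminative edges\n", nrow(x$truth_edges)))
  }
  invisible(x)
}
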