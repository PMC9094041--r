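#' Upper-triangle edge index
#'
#' The `p (p - 1) / 2` unordered ROI pairs in lexicographic (row-major)
#' order: (1,2), (1,3), ..., (1,p), (2,3), ...
#'
#' @param p number of ROIs.
#' @return integer matrix with columns `i`, `j` (`i < j`).
#' @export
edge_index <- function(p) {
  stopifnot(p >= 2)
  i <- rep(seq_len(p - 1L), times = (p - 1L):1L)
  j <- unlist(lapply(seq_len(p - 1L), function(a) (a + 1L):p))
  cbind(i = i, j = j)
}

#' Vectorise the upper triangle of a network
#'
#' Extracts the strictly-upper-triangular edge weights in the lexicographic
#' order of [edge_index()]; these are the classification features. A
#' 160-ROI atlas yields 12720 features.
#'
#' @param W square (symmetric or symmetrised) network matrix.
#' @return numeric vector of length `p (p - 1) / 2`.
#' @export
vectorize_upper_triangle <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) {
    stop("vectorize_upper_triangle expects a square matrix, got ",
         nrow(W), " x ", ncol(W), call. = FALSE)
  }
  t(W)[lower.tri(W)]
}

#' Estimate one subject's network by name
#'
#' Dispatcher used by the pipeline and the command line. `"sr"` output is
#' symmetrised by `(W + t(W)) / 2` before use as features; all other
#' estimators are symmetric by construction. `"bhm-w"` / `"bhm-omega"`
#' return the low- / high-order matrix of a BHM fit with the given `lam`.
#'
#' @param X time-series matrix.
#' @param method one of `"pc"`, `"shrunk-pc"`, `"sr"`, `"cc"`,
#'   `"soft-threshold"`, `"bhm-w"`, `"bhm-omega"`.
#' @param param estimator hyper-parameter (ignored by `"pc"` and `"cc"`).
#' @param delta BHM stabilisation ridge (default 0.1).
#' @return `bfn` network matrix.
#' @export
estimate_network <- function(X, method, param = NA, delta = 0.1) {
  method <- match.arg(method, c("pc", "shrunk-pc", "sr", "cc",
                                "soft-threshold", "bhm-w", "bhm-omega"))
  needs_param <- !(method %in% c("pc", "cc"))
  if (needs_param && (length(param) != 1 || is.na(param))) {
    stop("estimator '", method, "' needs a numeric parameter", call. = FALSE)
  }
  switch(method,
    "pc" = pc_network(X),
    "shrunk-pc" = shrunk_pc_network(X, param),
    "sr" = {
      W <- sr_network(X, param)
      new_bfn(sym(as.matrix(W)), "low", "sr-symmetrized", colnames(W))
    },
    "cc" = cc_network(pc_network(X)),
    "soft-threshold" = soft_threshold_network(X, param),
    "bhm-w" = fit_bhm(X, bhm_config(lam = param, delta = delta))$W,
    "bhm-omega" = fit_bhm(X, bhm_config(lam = param, delta = delta))$Omega
  )
}

#' Edge-feature table of a cohort
#'
#' Estimates one network per subject and stacks the vectorised upper
#' triangles into an `n_subjects x n_edges` matrix.
#'
#' @inheritParams estimate_network
#' @param cohort a `cohort` (see [simulate_cohort()] or [read_cohort_dir()]).
#' @return `feature_table` list: `matrix`, `edge_index`, `labels`.
#' @export
compute_features <- function(cohort, method, param = NA, delta = 0.1) {
  stopifnot(inherits(cohort, "cohort"))
  p <- ncol(cohort$subjects[[1]])
  n_edges <- p * (p - 1) / 2
  mat <- t(vapply(cohort$subjects,
                  function(X) vectorize_upper_triangle(
                    estimate_network(X, method, param, delta)),
                  numeric(n_edges)))
  structure(list(matrix = mat, edge_index = edge_index(p),
                 labels = cohort$labels),
            class = "feature_table")
}

# Vectorised two-sample t-test p-values over feature columns. Pooled
# variance by default; Welch with welch = TRUE. Degenerate columns: zero
# variance in both groups gives p = 1 when the group means agree and p = 0
# when they differ (an infinitely strong effect).
edge_ttest_pvalues <- function(mat, labels, welch = FALSE) {
  g0 <- labels == 0
  g1 <- labels == 1
  n0 <- sum(g0); n1 <- sum(g1)
  if (n0 < 2 || n1 < 2) {
    stop("two-sample t-test needs at least 2 subjects per class (have ",
         n0, " and ", n1, ")", call. = FALSE)
  }
  m0 <- colMeans(mat[g0, , drop = FALSE])
  m1 <- colMeans(mat[g1, , drop = FALSE])
  v0 <- apply(mat[g0, , drop = FALSE], 2, stats::var)
  v1 <- apply(mat[g1, , drop = FALSE], 2, stats::var)
  if (welch) {
    se2 <- v0 / n0 + v1 / n1
    df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  } else {
    sp2 <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
    se2 <- sp2 * (1 / n0 + 1 / n1)
    df <- rep(n0 + n1 - 2, length(se2))
  }
  tstat <- (m1 - m0) / sqrt(se2)
  pv <- 2 * stats::pt(-abs(tstat), df)
  zero_se <- !is.finite(tstat) | se2 == 0
  pv[zero_se & (m1 == m0)] <- 1
  pv[zero_se & (m1 != m0)] <- 0
  unname(pv)
}

#' Select discriminative edges by two-sample t-test
#'
#' Returns the indices of feature columns whose two-sample t-test p-value is
#' strictly below `p_threshold`. The test must be fitted on training
#' subjects only; the pipeline guarantees this by subsetting the feature
#' table before calling.
#'
#' @param features a `feature_table` (or a list with `matrix` and `labels`).
#' @param p_threshold significance threshold.
#' @param welch use the Welch (unequal-variance) test instead of the pooled
#'   one.
#' @return integer vector of selected column indices (possibly empty).
#' @export
ttest_select <- function(features, p_threshold, welch = FALSE) {
  pv <- edge_ttest_pvalues(features$matrix, features$labels, welch)
  unname(which(pv < p_threshold))
}

train_predict_svm <- function(x_train, y_train, x_test, cost, scale) {
  fit <- e1071::svm(x = x_train, y = factor(y_train, levels = c(0, 1)),
                    kernel = "linear", cost = cost, scale = scale)
  as.integer(as.character(stats::predict(fit, x_test)))
}

# Feature selection with fall-back: when no edge clears the threshold the
# single smallest-p edge is used so the classifier stays defined.
select_or_fallback <- function(mat, labels, p_threshold, welch, warn = FALSE) {
  pv <- edge_ttest_pvalues(mat, labels, welch)
  sel <- which(pv < p_threshold)
  if (length(sel) == 0) {
    if (warn) {
      warning("t-test selected no edges at p < ", p_threshold,
              "; falling back to the single smallest-p edge", call. = FALSE)
    }
    sel <- which.min(pv)
  }
  unname(sel)
}

#' Build an evaluation report from confusion counts
#'
#' @param tp,tn,fp,fn confusion counts; group 1 is the positive class.
#' @param extra named list appended to the report (per-fold logs etc.).
#' @return `eval_report` list with `acc = (tp + tn) / n`,
#'   `sen = tp / (tp + fn)`, `spe = tn / (tn + fp)`.
#' @export
eval_report <- function(tp, tn, fp, fn, extra = list()) {
  n <- tp + tn + fp + fn
  rep <- c(list(tp = tp, tn = tn, fp = fp, fn = fn,
                acc = (tp + tn) / n,
                sen = tp / (tp + fn),
                spe = tn / (tn + fp)),
           extra)
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> ACC %.4f  SEN %.4f  SPE %.4f  (tp %d, tn %d, fp %d, fn %d)\n",
              x$acc, x$sen, x$spe, x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

default_param_grid <- function(method) {
  switch(method,
    "pc" = NA_real_,
    "cc" = NA_real_,
    "sr" = 2^(-2:2),
    "shrunk-pc" = c(1e-4, 1e-3, 1e-2, 1e-1, 1),
    "soft-threshold" = c(0.05, 0.1, 0.2, 0.3, 0.4),
    "bhm-w" = c(1e-4, 1e-3, 1e-2, 1e-1, 1),
    "bhm-omega" = c(1e-4, 1e-3, 1e-2, 1e-1, 1),
    stop("unknown estimator '", method, "'", call. = FALSE)
  )
}

# Core nested-LOOCV loop over precomputed per-parameter feature matrices.
# feats: named list (one entry per parameter value) of n_subjects x n_edges
# matrices. combos: data.frame(param_idx, p_threshold) in tie-break order.
loocv_core <- function(feats, labels, combos, svm_C, scale_features, welch) {
  n_sub <- length(labels)
  pred <- integer(n_sub)
  chosen_param <- numeric(n_sub)
  chosen_p <- numeric(n_sub)
  selected_edges <- vector("list", n_sub)
  inner_needed <- nrow(combos) > 1
  for (t in seq_len(n_sub)) {
    train <- setdiff(seq_len(n_sub), t)
    best <- 1L
    if (inner_needed) {
      inner_acc <- numeric(nrow(combos))
      for (ci in seq_len(nrow(combos))) {
        mat <- feats[[combos$param_idx[ci]]]
        hits <- 0L
        for (u in train) {
          itrain <- setdiff(train, u)
          sel <- select_or_fallback(mat[itrain, , drop = FALSE],
                                    labels[itrain], combos$p_threshold[ci],
                                    welch)
          yhat <- train_predict_svm(mat[itrain, sel, drop = FALSE],
                                    labels[itrain],
                                    mat[u, sel, drop = FALSE],
                                    svm_C, scale_features)
          hits <- hits + (yhat == labels[u])
        }
        inner_acc[ci] <- hits / length(train)
      }
      best <- which.max(inner_acc)   # ties: first = smallest parameter
    }
    mat <- feats[[combos$param_idx[best]]]
    sel <- select_or_fallback(mat[train, , drop = FALSE], labels[train],
                              combos$p_threshold[best], welch, warn = TRUE)
    pred[t] <- train_predict_svm(mat[train, sel, drop = FALSE], labels[train],
                                 mat[t, sel, drop = FALSE],
                                 svm_C, scale_features)
    chosen_param[t] <- combos$param[best]
    chosen_p[t] <- combos$p_threshold[best]
    selected_edges[[t]] <- sel
  }
  list(pred = pred, chosen_param = chosen_param, chosen_p = chosen_p,
       selected_edges = selected_edges)
}

finish_report <- function(labels, core, p_threshold) {
  tp <- sum(core$pred == 1 & labels == 1)
  tn <- sum(core$pred == 0 & labels == 0)
  fp <- sum(core$pred == 1 & labels == 0)
  fn <- sum(core$pred == 0 & labels == 1)
  eval_report(tp, tn, fp, fn, extra = list(
    per_fold_predictions = data.frame(
      subject = seq_along(labels), truth = labels, pred = core$pred,
      param = core$chosen_param, p_threshold = core$chosen_p,
      n_features = lengths(core$selected_edges)),
    selected_lambda_per_fold = core$chosen_param,
    selected_edges_per_fold = core$selected_edges,
    p_threshold = p_threshold))
}

#' Nested leave-one-out cross-validated classification
#'
#' The full evaluation protocol: per-subject networks are estimated for
#' every value of the hyper-parameter grid, edge weights become features,
#' and an outer leave-one-out loop measures classification of group 1
#' (positive class) versus group 0. Inside each outer fold an inner
#' leave-one-out loop over the training subjects picks the grid value (and,
#' when `p_threshold` has several values, the selection threshold) with the
#' best inner accuracy, ties going to the smallest value. Edge selection
#' (two-sample t-test, see [ttest_select()]) and the linear SVM are fitted
#' on training subjects only. When selection returns no edge, the single
#' smallest-p edge is used (with a warning).
#'
#' @inheritParams compute_features
#' @param param_grid numeric hyper-parameter grid; `NULL` uses the
#'   estimator's default grid (a singleton for the parameter-free `"pc"`
#'   and `"cc"`, for which no inner loop is run).
#' @param p_threshold t-test selection threshold(s); a vector is searched by
#'   the inner loop jointly with `param_grid`.
#' @param svm_C linear SVM cost (default 1).
#' @param scale_features standardise features inside the SVM (default
#'   `FALSE`).
#' @param welch use Welch's t-test for selection (default pooled).
#' @return `eval_report` with confusion counts, ACC/SEN/SPE and per-fold
#'   logs.
#' @export
evaluate_loocv <- function(cohort, method, param_grid = NULL,
                           p_threshold = 0.05, svm_C = 1,
                           scale_features = FALSE, welch = FALSE,
                           delta = 0.1) {
  stopifnot(inherits(cohort, "cohort"))
  if (length(unique(cohort$labels)) != 2) {
    stop("cohort must contain both classes", call. = FALSE)
  }
  param_grid <- sort(param_grid %||% default_param_grid(method), na.last = TRUE)
  feats <- lapply(param_grid,
                  function(v) compute_features(cohort, method, v, delta)$matrix)
  evaluate_loocv_features(feats, cohort$labels, param_grid, p_threshold,
                          svm_C, scale_features, welch)
}

#' Nested LOOCV on precomputed feature matrices
#'
#' Same protocol as [evaluate_loocv()] but starting from features, one
#' `n_subjects x n_edges` matrix per hyper-parameter value. Useful for
#' features built outside the package and for leakage audits.
#'
#' @param feats single feature matrix, `feature_table`, or list of matrices
#'   (one per value of `param_grid`).
#' @param labels 0/1 class labels.
#' @param param_grid hyper-parameter value attached to each feature matrix.
#' @inheritParams evaluate_loocv
#' @return `eval_report`.
#' @export
evaluate_loocv_features <- function(feats, labels, param_grid = NA,
                                    p_threshold = 0.05, svm_C = 1,
                                    scale_features = FALSE, welch = FALSE) {
  if (inherits(feats, "feature_table")) feats <- list(feats$matrix)
  if (is.matrix(feats)) feats <- list(feats)
  stopifnot(length(feats) == length(param_grid))
  p_threshold <- sort(p_threshold)
  combos <- expand.grid(p_threshold = p_threshold,
                        param_idx = seq_along(param_grid))
  combos <- combos[order(combos$param_idx, combos$p_threshold), ]
  combos$param <- param_grid[combos$param_idx]
  core <- loocv_core(feats, labels, combos, svm_C, scale_features, welch)
  finish_report(labels, core, p_threshold)
}

#' Accuracy over a hyper-parameter and threshold grid
#'
#' Runs [evaluate_loocv()] once per `(param, p_threshold)` combination with
#' the swept value held fixed (no inner selection loop), the protocol behind
#' parameter-sensitivity curves. The headline "best over grid" number that
#' this table supports is optimistic — the grid is chosen on the same data —
#' and is reported as such.
#'
#' @inheritParams evaluate_loocv
#' @param param_values hyper-parameter values to sweep (use `NA` for the
#'   parameter-free estimators).
#' @param p_values t-test thresholds to sweep.
#' @return data.frame with columns `param`, `p_threshold`, `acc`, `sen`,
#'   `spe`.
#' @export
parameter_sweep <- function(cohort, method, param_values, p_values,
                            svm_C = 1, scale_features = FALSE,
                            welch = FALSE, delta = 0.1) {
  stopifnot(length(param_values) >= 1, length(p_values) >= 1)
  rows <- list()
  for (pv in param_values) {
    feats <- list(compute_features(cohort, method, pv, delta)$matrix)
    for (pt in p_values) {
      rep <- evaluate_loocv_features(feats, cohort$labels, pv, pt,
                                     svm_C, scale_features, welch)
      rows[[length(rows) + 1]] <- data.frame(
        param = pv, p_threshold = pt,
        acc = rep$acc, sen = rep$sen, spe = rep$spe)
    }
  }
  do.call(rbind, rows)
}
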