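# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

sym <- function(M) (M + t(M)) / 2

fnorm <- function(M) sqrt(sum(M^2))

# Inverse of a symmetric positive definite matrix via Cholesky; the error
# message carries `context` so callers can name the offending iterate.
inv_spd <- function(M, context = "matrix") {
  R <- tryCatch(chol(M), error = function(e) {
    stop(context, " is not positive definite (Cholesky factorisation failed)",
         call. = FALSE)
  })
  chol2inv(R)
}

log_det_spd <- function(M, context = "matrix") {
  R <- tryCatch(chol(M), error = function(e) {
    stop(context, " is not positive definite (Cholesky factorisation failed)",
         call. = FALSE)
  })
  2 * sum(log(diag(R)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
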