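#' Network matrix objects
#'
#' Estimated networks are plain `p x p` numeric matrices carrying two
#' attributes: `order_tag` (`"low"` for signal-level connectivity, `"high"`
#' for connectivity-of-connectivity) and `estimator_tag` (provenance, e.g.
#' `"pc"`, `"sr"`, `"bhm-omega"`). ROI names, when known, are stored as
#' dimnames.
#'
#' @param values numeric `p x p` matrix.
#' @param order_tag `"low"` or `"high"`.
#' @param estimator_tag short provenance string.
#' @param roi_names optional character vector of length `p`.
#' @return a `bfn` object (a classed matrix).
#' @export
new_bfn <- function(values, order_tag, estimator_tag, roi_names = NULL) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  order_tag <- match.arg(order_tag, c("low", "high"))
  if (!all(is.finite(values))) {
    stop("network matrix contains non-finite entries", call. = FALSE)
  }
  if (!is.null(roi_names)) dimnames(values) <- list(roi_names, roi_names)
  structure(values,
            class = c("bfn", class(values)),
            order_tag = order_tag,
            estimator_tag = estimator_tag)
}

#' @export
print.bfn <- function(x, ...) {
  cat(sprintf("<bfn> %s-order network (%s), %d x %d ROIs\n",
              attr(x, "order_tag"), attr(x, "estimator_tag"),
              nrow(x), ncol(x)))
  cat(sprintf("  edge weights: min %.4f, median %.4f, max %.4f\n",
              min(x), stats::median(x), max(x)))
  invisible(x)
}

#' @export
as.matrix.bfn <- function(x, ...) {
  attributes(x) <- list(dim = dim(x), dimnames = dimnames(x))
  x
}

roi_labels <- function(W) {
  colnames(W) %||% paste0("ROI", seq_len(ncol(W)))
}
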