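#' Validate an ROI time-series matrix
#'
#' A time-series matrix holds one subject's parcellated rs-fMRI signals:
#' rows are time points, columns are regions of interest (ROIs). Column
#' names, when present, are kept as ROI identifiers.
#'
#' @param X numeric matrix (or object coercible to one) with `n >= 2` rows
#'   (time points) and `p >= 2` columns (ROIs); all entries must be finite.
#' @return the validated numeric matrix.
#' @export
as_timeseries <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("time series must be a numeric matrix (rows = time points, columns = ROIs)",
         call. = FALSE)
  }
  if (nrow(X) < 2) {
    stop("time series needs at least 2 time points, got ", nrow(X), call. = FALSE)
  }
  if (ncol(X) < 2) {
    stop("time series needs at least 2 ROIs, got ", ncol(X), call. = FALSE)
  }
  if (!all(is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1, ]
    stop("non-finite value at row ", bad[1], ", column ", bad[2], call. = FALSE)
  }
  X
}

#' Centre and unit-normalise ROI signals
#'
#' Each ROI signal is centred (mean removed) and scaled to unit Euclidean
#' norm, so that the cross-product of two normalised columns is their sample
#' Pearson correlation. The operation is idempotent up to floating point.
#'
#' @param X time-series matrix, see [as_timeseries()].
#' @return matrix of the same shape; every column has mean 0 and norm 1.
#' @examples
#' normalize_signals(cbind(a = c(1, 2, 3), b = c(2, 0, 1)))
#' @export
normalize_signals <- function(X) {
  X <- as_timeseries(X)
  ctr <- sweep(X, 2, colMeans(X), "-")
  nrm <- sqrt(colSums(ctr^2))
  flat <- which(nrm == 0)
  if (length(flat)) {
    stop("zero-variance (flat) ROI signal in column(s) ",
         paste(flat, collapse = ", "),
         "; a constant column carries no connectivity information",
         call. = FALSE)
  }
  sweep(ctr, 2, nrm, "/")
}
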