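#' Read an ROI time-series matrix from delimited text
#'
#' Rows are time points, columns are ROIs. A single header row of ROI names
#' is auto-detected (any non-numeric field in the first row). The delimiter
#' is inferred from the extension (`.tsv` / `.txt` = tab, otherwise comma)
#' unless given. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param delim field delimiter; `NULL` to infer from the extension.
#' @return validated numeric matrix with ROI names as column names when a
#'   header was present.
#' @export
read_timeseries <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- delim %||%
    (if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ",")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("file is empty: ", path, call. = FALSE)
  # appending one delimiter keeps trailing blank fields (strsplit drops them)
  cells <- strsplit(paste0(lines, delim), delim, fixed = TRUE)
  cells <- lapply(cells, trimws)
  widths <- lengths(cells)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    stop("ragged input: row ", bad, " has ", widths[bad],
         " fields, expected ", widths[1], call. = FALSE)
  }
  first_num <- suppressWarnings(as.numeric(cells[[1]]))
  roi_names <- NULL
  if (anyNA(first_num)) {
    roi_names <- cells[[1]]
    cells <- cells[-1]
    if (length(cells) == 0) stop("no data rows after header", call. = FALSE)
  }
  vals <- suppressWarnings(vapply(cells, as.numeric, numeric(widths[1])))
  X <- t(matrix(vals, nrow = widths[1]))
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    raw <- cells[[bad[1]]][bad[2]]
    stop("non-numeric or blank cell at data row ", bad[1], ", column ",
         bad[2], " (\"", raw, "\")", call. = FALSE)
  }
  colnames(X) <- roi_names
  as_timeseries(X)
}

format_full <- function(x) sprintf("%.17g", x)

#' Write a network matrix to text
#'
#' `"adjacency-csv"` writes the dense matrix with ROI names as header and
#' index column, preceded by a comment line holding `order_tag` and
#' `estimator_tag`; values are printed with 17 significant digits so the
#' read-back ([read_network()]) reproduces them to full double precision.
#' `"edgelist-tsv"` writes one `roi_i, roi_j, weight` row per unordered pair
#' `i < j`.
#'
#' @param W a `bfn` (or plain square matrix).
#' @param path output file path.
#' @param format `"adjacency-csv"` or `"edgelist-tsv"`.
#' @export
write_network <- function(W, path, format = c("adjacency-csv", "edgelist-tsv")) {
  format <- match.arg(format)
  M <- as.matrix(W)
  stopifnot(nrow(M) == ncol(M))
  labels <- roi_labels(M)
  tag_line <- sprintf("# order_tag=%s estimator_tag=%s",
                      attr(W, "order_tag") %||% "low",
                      attr(W, "estimator_tag") %||% "unknown")
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing", call. = FALSE)
  })
  on.exit(close(con))
  if (format == "adjacency-csv") {
    writeLines(tag_line, con)
    writeLines(paste(c("", labels), collapse = ","), con)
    for (r in seq_len(nrow(M))) {
      writeLines(paste(c(labels[r], format_full(M[r, ])), collapse = ","), con)
    }
  } else {
    ei <- edge_index(nrow(M))
    writeLines(tag_line, con)
    writeLines("roi_i\troi_j\tweight", con)
    writeLines(sprintf("%s\t%s\t%s", labels[ei[, 1]], labels[ei[, 2]],
                       format_full(M[ei])), con)
  }
  invisible(path)
}

#' Read an adjacency-CSV network written by [write_network()]
#'
#' @param path file path.
#' @return `bfn` with tags restored from the header comment.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  order_tag <- "low"; estimator_tag <- "unknown"
  tagl <- grep("^#", lines, value = TRUE)
  if (length(tagl)) {
    m1 <- regmatches(tagl[1], regexec("order_tag=(\\S+)", tagl[1]))[[1]]
    m2 <- regmatches(tagl[1], regexec("estimator_tag=(\\S+)", tagl[1]))[[1]]
    if (length(m1) == 2) order_tag <- m1[2]
    if (length(m2) == 2) estimator_tag <- m2[2]
  }
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]][-1]
  rows <- strsplit(lines[-1], ",", fixed = TRUE)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]),
                   numeric(length(header))))
  new_bfn(vals, order_tag, estimator_tag, header)
}

#' Write a cohort to a directory
#'
#' One `subject_NNN.csv` time-series file per subject, a `labels.tsv` with
#' `subject_id` / `label` columns, and a `truth.json` with the planted edge
#' list and perturbation covariance when present.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if missing).
#' @export
write_cohort_dir <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("subject_%03d", seq_along(cohort$subjects))
  for (s in seq_along(cohort$subjects)) {
    X <- cohort$subjects[[s]]
    utils::write.table(
      matrix(format_full(X), nrow(X), ncol(X)),
      file.path(dir, paste0(ids[s], ".csv")),
      sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  utils::write.table(
    data.frame(subject_id = ids, label = cohort$labels),
    file.path(dir, "labels.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  truth <- list()
  if (!is.null(cohort$truth_edges)) truth$edges <- unname(cohort$truth_edges)
  if (!is.null(cohort$truth_omega)) truth$omega <- unname(cohort$truth_omega)
  if (length(truth)) {
    jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA)
  }
  invisible(dir)
}

#' Read a cohort directory
#'
#' Expects the layout written by [write_cohort_dir()]: per-subject
#' time-series CSVs and a `labels.tsv` mapping file names (without
#' extension) to 0/1 labels.
#'
#' @param dir directory path.
#' @return a `cohort`.
#' @export
read_cohort_dir <- function(dir) {
  lab_path <- file.path(dir, "labels.tsv")
  if (!file.exists(lab_path)) {
    stop("labels.tsv not found in ", dir, call. = FALSE)
  }
  lab <- utils::read.table(lab_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("subject_id", "label") %in% names(lab))) {
    stop("labels.tsv must have subject_id and label columns", call. = FALSE)
  }
  if (!all(lab$label %in% c(0, 1))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  subjects <- lapply(lab$subject_id, function(id) {
    read_timeseries(file.path(dir, paste0(id, ".csv")))
  })
  truth_edges <- NULL; truth_omega <- NULL
  tpath <- file.path(dir, "truth.json")
  if (file.exists(tpath)) {
    truth <- jsonlite::read_json(tpath, simplifyVector = TRUE)
    if (!is.null(truth$edges)) {
      truth_edges <- matrix(as.integer(truth$edges), ncol = 2,
                            dimnames = list(NULL, c("i", "j")))
    }
    if (!is.null(truth$omega)) truth_omega <- as.matrix(truth$omega)
  }
  structure(list(subjects = subjects, labels = as.integer(lab$label),
                 truth_edges = truth_edges, truth_omega = truth_omega,
                 spec = NULL),
            class = "cohort")
}
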