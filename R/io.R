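#' Read a sample-by-feature matrix from CSV/TSV
#'
#' Expects a header row of feature names and a first column of sample
#' identifiers; all remaining cells must be finite numbers.
#'
#' @param path file path.
#' @param sep field delimiter; `","` for CSV (default), `"\t"` for TSV.
#' @return a numeric matrix with sample IDs as rownames and feature names as
#'   colnames.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(id = c("s1", "s2"), x = c(1, 2), y = c(3, 4)),
#'           f, row.names = FALSE)
#' read_feature_matrix(f)
#' @export
read_feature_matrix <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   colClasses = "character", comment.char = "")
  if (ncol(df) < 2) stop("expected an ID column plus at least one feature: ", path)
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicated sample IDs in ", path)
  vals <- df[, -1, drop = FALSE]
  x <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(ids, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric or non-finite value in %s at row %d, column '%s'",
                   path, bad[1], colnames(vals)[j]))
    x[, j] <- v
  }
  check_feature_matrix(x)
  x
}

#' Write a square sample-by-sample matrix (counts or affinity) as CSV
#'
#' Sample IDs appear both as the header and as the first column, so the file
#' round-trips through [read_feature_matrix()].
#'
#' @param m square numeric matrix with identical row and column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_square_matrix <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m),
            identical(rownames(m), colnames(m)))
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Validate the FeatureMatrix contract: finite numeric matrix, n >= 2, p >= 1,
# unique sample and feature identifiers (synthesized if absent).
check_feature_matrix <- function(x, min_n = 2L) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) stop("'x' must be a numeric matrix")
  if (nrow(x) < min_n) stop("need at least ", min_n, " samples")
  if (ncol(x) < 1L) stop("need at least one feature")
  if (any(!is.finite(x))) stop("'x' must not contain NA/NaN/Inf")
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("sample IDs must be unique")
  if (anyDuplicated(colnames(x))) stop("feature names must be unique")
  x
}
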