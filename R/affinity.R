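#' Single-tree leaf co-occurrence indicator
#'
#' Binary n-by-n matrix with a 1 wherever two samples land in the same leaf
#' of the tree (diagonal included: a sample always co-occurs with itself).
#'
#' @param tree an `urf_tree`.
#' @param x numeric sample-by-feature matrix.
#' @return symmetric binary integer matrix with sample IDs as dimnames.
#' @export
tree_cooccurrence <- function(tree, x) {
  x <- check_feature_matrix(x, min_n = 1L)
  l <- assign_leaves(tree, x)
  m <- matrix(as.integer(outer(l, l, "==")), length(l), length(l),
              dimnames = list(rownames(x), rownames(x)))
  m
}

#' Leaf co-occurrence counts over a forest
#'
#' Element-wise sum of the per-tree binary co-occurrence matrices. Every
#' sample is propagated through every tree (including trees it was out of the
#' bootstrap resample for), so the diagonal equals the number of trees.
#'
#' @param object an `urf_forest` or `urf_federated` model.
#' @param x numeric sample-by-feature matrix on the fit-time feature schema.
#' @return symmetric nonnegative integer matrix of class `urf_counts`.
#' @seealso [normalize_affinity()], [multiomics_counts()]
#' @export
forest_counts <- function(object, x) {
  stopifnot(inherits(object, c("urf_forest", "urf_federated")))
  if (length(object$trees) < 1L) stop("model contains no trees")
  x <- check_feature_matrix(x, min_n = 1L)
  counts <- .forest_counts_cpp(object$trees, x)
  dimnames(counts) <- list(rownames(x), rownames(x))
  structure(counts, class = c("urf_counts", class(counts)))
}

#' Normalize co-occurrence counts to an affinity matrix
#'
#' Divides the count matrix by its maximal entry, giving affinities in
#' \eqn{[0, 1]} with a unit diagonal (the diagonal carries the maximal count:
#' a sample shares a leaf with itself in every tree).
#'
#' @param counts symmetric nonnegative count matrix.
#' @return symmetric numeric matrix in \eqn{[0, 1]} of class `urf_affinity`.
#' @examples
#' normalize_affinity(matrix(c(5, 2, 2, 5), 2))
#' @export
normalize_affinity <- function(counts) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts))
  m <- max(counts)
  if (m <= 0) stop("count matrix is all zero; cannot normalize")
  structure(unclass(counts) / m, class = c("urf_affinity", "matrix", "array"))
}

#' Fuse leaf co-occurrence counts across omics layers
#'
#' Late fusion for multi-omics data: one forest is grown per layer, the raw
#' count matrices are summed element-wise, and the caller normalizes the sum
#' once with [normalize_affinity()]. All layers must cover the same samples
#' in the same order.
#'
#' @param forests list of `urf_forest` objects, one per layer.
#' @param xs list of sample-by-feature matrices over identical samples, in
#'   the same order as `forests`.
#' @return summed count matrix of class `urf_counts`.
#' @export
multiomics_counts <- function(forests, xs) {
  stopifnot(is.list(forests), is.list(xs), length(forests) == length(xs),
            length(forests) >= 1L)
  xs <- lapply(xs, check_feature_matrix, min_n = 1L)
  ids <- rownames(xs[[1]])
  for (l in seq_along(xs)) {
    if (!identical(rownames(xs[[l]]), ids))
      stop("sample IDs of omics layer ", l,
           " do not match layer 1 (same samples, same order, required)")
  }
  total <- forest_counts(forests[[1]], xs[[1]])
  for (l in seq_along(xs)[-1])
    total <- total + forest_counts(forests[[l]], xs[[l]])
  structure(total, dimnames = list(ids, ids),
            class = c("urf_counts", "matrix", "array"))
}

#' Affinity matrix in one step
#'
#' Convenience wrapper: fit one forest per input layer, sum the leaf
#' co-occurrence counts and normalize by the maximal entry.
#'
#' @param x a sample-by-feature matrix, or a list of such matrices (one per
#'   omics layer, identical samples in identical order).
#' @param ... forest parameters passed to [urf_fit()].
#' @param seed optional integer seed (fanned out per layer).
#' @return an `urf_affinity` matrix with the fitted forest(s) attached as
#'   attribute `"forests"`.
#' @examples
#' d <- make_equal_globular(sd = 0.1, seed = 1)
#' a <- urf_affinity(d$x, n_trees = 50, seed = 1)
#' range(a)
#' @export
urf_affinity <- function(x, ..., seed = NULL) {
  xs <- if (is.list(x) && !is.data.frame(x)) x else list(x)
  seeds <- if (is.null(seed)) vector("list", length(xs))
           else as.list(derive_seeds(seed, length(xs)))
  forests <- mapply(function(xi, si) urf_fit(xi, ..., seed = si),
                    xs, seeds, SIMPLIFY = FALSE)
  a <- normalize_affinity(multiomics_counts(forests, xs))
  attr(a, "forests") <- forests
  a
}
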