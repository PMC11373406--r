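#' Fit an unsupervised random forest
#'
#' Grows `n_trees` binary trees without any response variable. At each node a
#' random subset of `mtry` features is drawn and the split minimizing the
#' Fixation-Index-style score (see [split_score()]) is taken; a node becomes a
#' leaf when it holds fewer than `2 * min_leaf_size` samples or no candidate
#' feature admits a valid split. Samples are routed left when
#' `value <= threshold`.
#'
#' Defaults follow the settings used for two-dimensional benchmark scenarios
#' (500 trees, minimum leaf size 5, one candidate feature per node). For
#' higher-dimensional tabular data, 100 trees with `mtry = 2` work well: the
#' strong randomization of a small candidate set is beneficial when the goal
#' is an affinity matrix rather than prediction.
#'
#' @param x numeric sample-by-feature matrix (rownames are sample IDs).
#' @param n_trees number of trees.
#' @param mtry number of candidate features drawn uniformly without
#'   replacement at each node.
#' @param min_leaf_size minimum number of training samples per leaf.
#' @param bootstrap if `TRUE` (default), each tree is grown on a
#'   with-replacement resample of the rows, which decorrelates the trees (the
#'   split search is deterministic given a node and a candidate feature, so
#'   without resampling tree diversity comes from the `mtry` draws alone);
#'   affinity computation always propagates all samples through every tree
#'   regardless.
#' @param seed optional integer; the same seed yields an identical forest.
#'   The caller's RNG state is left untouched.
#' @return an object of class `urf_forest`: a list with elements `trees`
#'   (each of class `urf_tree`, a list of parallel node vectors `feature`,
#'   `threshold`, `left`, `right`, `leaf_id`, `n_train`), `params`, `p` and
#'   `feature_names`.
#' @examples
#' x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 5), 20))
#' fit <- urf_fit(x, n_trees = 50, seed = 1)
#' fit
#' @seealso [urf_affinity()], [forest_counts()], [assign_leaves()]
#' @export
urf_fit <- function(x, n_trees = 500L, mtry = 1L, min_leaf_size = 5L,
                    bootstrap = TRUE, seed = NULL) {
  x <- check_feature_matrix(x, min_n = 1L)
  n_trees <- as.integer(n_trees)
  mtry <- as.integer(mtry)
  min_leaf_size <- as.integer(min_leaf_size)
  stopifnot(n_trees >= 1L, min_leaf_size >= 1L,
            mtry >= 1L, mtry <= ncol(x))
  trees <- with_seed(seed,
    .grow_forest_cpp(x, n_trees, mtry, min_leaf_size, isTRUE(bootstrap), FALSE))
  trees <- lapply(trees, function(t) structure(t, class = "urf_tree"))
  structure(list(
    trees = trees,
    params = list(n_trees = n_trees, mtry = mtry,
                  min_leaf_size = min_leaf_size,
                  bootstrap = isTRUE(bootstrap), seed = seed),
    p = ncol(x),
    feature_names = colnames(x)
  ), class = "urf_forest")
}

#' @export
print.urf_forest <- function(x, ...) {
  cat("Unsupervised random forest\n")
  cat(sprintf("  trees: %d  mtry: %d  min leaf size: %d  bootstrap: %s\n",
              x$params$n_trees, x$params$mtry, x$params$min_leaf_size,
              x$params$bootstrap))
  cat(sprintf("  features at fit time: %d\n", x$p))
  nl <- vapply(x$trees, function(t) sum(!is.na(t$leaf_id)), integer(1))
  cat(sprintf("  leaves per tree: median %d (range %d-%d)\n",
              as.integer(median(nl)), min(nl), max(nl)))
  invisible(x)
}

#' Fixation-Index-style split score
#'
#' For a candidate feature's values `x` at a node and a proposed left/right
#' partition, returns the mean squared pairwise difference within the two
#' children (averaged over children; ordered pairs, denominator `N (N - 1)`;
#' a singleton child contributes 0) divided by the mean squared difference
#' between children (denominator `N_left * N_right`). Lower is better; 0 means
#' each child is internally constant. When the between-child spread is zero
#' (all values identical) the split is invalid and `NA` is returned.
#'
#' @param x numeric vector of the candidate feature's values at the node.
#' @param left logical vector marking the samples sent to the left child.
#' @return a single number, or `NA` for a degenerate split.
#' @examples
#' split_score(c(0, 0, 0, 10, 10, 10), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
split_score <- function(x, left) {
  .delta_f_cpp(as.numeric(x), as.logical(left))
}

#' Exhaustive best split over a candidate feature set
#'
#' Scans, for each candidate feature, thresholds at the midpoints between
#' consecutive distinct sorted values and returns the (feature, threshold)
#' pair minimizing [split_score()] among splits leaving at least
#' `min_leaf_size` samples in each child. Ties are broken toward the lowest
#' feature index, then the lowest threshold.
#'
#' @param x numeric matrix of the samples at the node.
#' @param candidates integer vector of candidate column indices.
#' @param min_leaf_size minimum child size.
#' @return a list with `feature`, `threshold` and `score`, or `NULL` when no
#'   valid split exists (all candidates constant or the leaf-size constraint
#'   cannot be met).
#' @export
best_split <- function(x, candidates = seq_len(ncol(x)), min_leaf_size = 5L) {
  x <- check_feature_matrix(x, min_n = 1L)
  candidates <- sort(unique(as.integer(candidates)))
  stopifnot(all(candidates >= 1L), all(candidates <= ncol(x)))
  res <- .best_split_cpp(x, candidates, as.integer(min_leaf_size))
  if (is.na(res$feature)) NULL else res
}

#' Route samples to leaves
#'
#' Traverses a fitted tree with each row of `x` (left when
#' `value <= threshold`) and returns the leaf identifier reached.
#'
#' @param tree an `urf_tree` (an element of `urf_forest$trees`).
#' @param x numeric matrix whose columns are indexed consistently with the
#'   data the tree was grown on.
#' @return integer vector of leaf IDs, one per row of `x`.
#' @export
assign_leaves <- function(tree, x) {
  stopifnot(inherits(tree, "urf_tree"))
  x <- check_feature_matrix(x, min_n = 1L)
  setNames(.leaf_ids_cpp(tree, x), rownames(x))
}

# n-by-T matrix of leaf ids: sample i in tree t
leaf_matrix <- function(forest, x) {
  .leaf_matrix_cpp(forest$trees, x)
}
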