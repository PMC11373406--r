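#' Tree-count stability curves for selecting the number of clusters
#'
#' Model-internal k selection. A full forest is fitted and its Ward
#' clustering at each candidate k is taken as the reference solution. The
#' number of trees is then reduced (random tree subsets, `n_reps` per count)
#' and the agreement between the reduced-forest solution and the reference is
#' tracked with the Adjusted Rand Index. A k whose curve stays flat as trees
#' are removed is supported by many independent trees and can be trusted; a k
#' whose curve drops reflects fine structure that only the full ensemble
#' resolves.
#'
#' Two notions of the reduced-forest solution are available:
#' \describe{
#'   \item{`"recluster"` (default)}{the affinity matrix is recomputed from
#'     the tree subset and Ward-cut at k; the curve measures how many trees
#'     the clustering itself needs to stabilize.}
#'   \item{`"classifier"`}{the forest predicts the reference labels: each
#'     leaf is labeled by the majority reference label of the samples it
#'     holds (ties to the lowest label) and each sample is relabeled by
#'     majority vote over its per-tree leaf labels.}
#' }
#'
#' @param x sample-by-feature matrix.
#' @param k_range candidate cluster numbers.
#' @param tree_counts decreasing tree counts to evaluate; defaults to 100%,
#'   50%, 20%, 10% and 4% of `n_trees`.
#' @param n_reps random tree subsets per reduced count.
#' @param method `"recluster"` or `"classifier"` (see Details).
#' @param n_trees,mtry,min_leaf_size,bootstrap forest parameters.
#' @param seed integer seed for the forest and the tree subsets.
#' @return data.frame of class `urf_stability` with columns `k`, `n_trees`,
#'   `replicate`, `ari`; the reference labels per k are in attribute
#'   `"reference"`.
#' @seealso [select_k_stability()], [silhouette_select_k()]
#' @export
stability_curves <- function(x, k_range = 2:5, tree_counts = NULL,
                             n_reps = 10L, method = c("recluster", "classifier"),
                             n_trees = 500L, mtry = 2L,
                             min_leaf_size = 5L, bootstrap = TRUE,
                             seed = NULL) {
  x <- check_feature_matrix(x)
  method <- match.arg(method)
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(min(k_range) >= 2L)
  if (is.null(tree_counts))
    tree_counts <- unique(pmax(1L, round(n_trees * c(1, 0.5, 0.2, 0.1, 0.04))))
  tree_counts <- sort(unique(as.integer(tree_counts)), decreasing = TRUE)
  stopifnot(max(tree_counts) <= n_trees, min(tree_counts) >= 1L)
  seeds <- derive_seeds(seed, 2L)
  forest <- urf_fit(x, n_trees = n_trees, mtry = mtry,
                    min_leaf_size = min_leaf_size, bootstrap = bootstrap,
                    seed = seeds[1])
  d <- affinity_to_distance(normalize_affinity(forest_counts(forest, x)))
  hc <- hclust(as.dist(d), method = "ward.D2")
  reference <- lapply(setNames(k_range, k_range),
                      function(k) cutree(hc, k = k))
  n <- nrow(x); T <- n_trees
  # one subset per (tree count, replicate), shared across k
  subsets <- with_seed(seeds[2], {
    out <- list()
    for (tc in tree_counts) for (r in seq_len(n_reps))
      out[[length(out) + 1L]] <- list(
        tc = tc, rep = r,
        sel = if (tc == T) seq_len(T) else sample.int(T, tc))
    out
  })
  res <- vector("list", length(subsets) * length(k_range)); row <- 0L
  if (method == "recluster") {
    for (su in subsets) {
      counts <- .forest_counts_cpp(forest$trees[su$sel], x)
      hc_red <- hclust(as.dist(1 - counts / max(counts)), method = "ward.D2")
      for (k in k_range) {
        row <- row + 1L
        res[[row]] <- data.frame(
          k = k, n_trees = su$tc, replicate = su$rep,
          ari = adjusted_rand_index(cutree(hc_red, k = k),
                                    reference[[as.character(k)]]))
      }
    }
  } else {
    leaves <- leaf_matrix(forest, x)                  # n x T leaf ids
    for (k in k_range) {
      ref <- reference[[as.character(k)]]
      pred_tree <- matrix(0L, n, T)
      for (t in seq_len(T)) {
        leaf_lab <- vapply(split(ref, leaves[, t]),
                           function(v) which.max(tabulate(v, k)), integer(1))
        pred_tree[, t] <- leaf_lab[as.character(leaves[, t])]
      }
      for (su in subsets) {
        m <- sapply(seq_len(k), function(l)
          rowSums(pred_tree[, su$sel, drop = FALSE] == l))
        pred <- max.col(m, ties.method = "first")     # ties -> lowest label
        row <- row + 1L
        res[[row]] <- data.frame(k = k, n_trees = su$tc, replicate = su$rep,
                                 ari = adjusted_rand_index(pred, ref))
      }
    }
  }
  out <- do.call(rbind, res)
  out <- out[order(out$k, -out$n_trees, out$replicate), ]
  rownames(out) <- NULL
  structure(out, reference = reference,
            class = c("urf_stability", "data.frame"))
}

#' Heuristic k from stability curves
#'
#' Returns the largest k whose median ARI drop between the full forest and
#' the smallest tree count stays below `drop_tol`. The curves themselves are
#' the primary output of [stability_curves()] — visual inspection is
#' recommended — and this heuristic is an opt-in summary of them.
#'
#' @param curves an `urf_stability` data.frame.
#' @param drop_tol tolerated median ARI drop (default 0.05).
#' @return the selected k, with the per-k median drops attached as attribute
#'   `"drops"`.
#' @export
select_k_stability <- function(curves, drop_tol = 0.05) {
  stopifnot(inherits(curves, "urf_stability"))
  ks <- sort(unique(curves$k))
  full <- max(curves$n_trees); small <- min(curves$n_trees)
  drops <- vapply(ks, function(k) {
    median(curves$ari[curves$k == k & curves$n_trees == full]) -
      median(curves$ari[curves$k == k & curves$n_trees == small])
  }, numeric(1))
  ok <- ks[drops < drop_tol]
  if (length(ok) == 0L)
    stop("no k in the curves is stable at drop_tol = ", drop_tol)
  structure(max(ok), drops = setNames(drops, ks))
}

#' @export
plot.urf_stability <- function(x, ...) {
  ks <- sort(unique(x$k))
  tcs <- sort(unique(x$n_trees), decreasing = TRUE)
  med <- sapply(ks, function(k) vapply(tcs, function(tc)
    median(x$ari[x$k == k & x$n_trees == tc]), numeric(1)))
  graphics::matplot(tcs, med, type = "b", pch = 19, lty = 1,
                    xlim = rev(range(tcs)), ylim = c(0, 1.02),
                    xlab = "number of trees", ylab = "median ARI vs reference",
                    ...)
  graphics::legend("bottomleft", legend = paste0("k=", ks),
                   col = seq_along(ks), lty = 1, pch = 19, bty = "n")
  invisible(x)
}
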