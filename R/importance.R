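#' Cluster-specific feature importance (one-vs-all)
#'
#' Given a fitted unsupervised forest and a cluster solution, quantifies how
#' much each feature contributes to isolating each cluster. For cluster c the
#' labels are binarized (c vs rest) and, for every internal node of every
#' tree, the decrease in Gini impurity induced by the *existing* unsupervised
#' split is computed,
#' \deqn{\Delta I = I(t) - [N(t_L) I(t_L) + N(t_R) I(t_R)] / N(t),}
#' weighted by the fraction of samples reaching the node, accumulated on the
#' node's split feature, and averaged over trees. Splits are never re-learned:
#' training stays unsupervised, the labels only score the splits.
#'
#' @param forest an `urf_forest` fitted on `x`'s feature schema.
#' @param x sample-by-feature matrix.
#' @param labels cluster labels, one per row of `x` (an integer vector or an
#'   `urf_clusters` object); every cluster must be nonempty.
#' @param normalize if `TRUE` (default) each cluster's scores are divided by
#'   their sum, so rows sum to 1 whenever any split exists; the raw mean
#'   impurity decreases are kept in attribute `"raw"`.
#' @return numeric clusters-by-features matrix of class `urf_importance`;
#'   features never used in any split score exactly 0.
#' @export
cluster_importance <- function(forest, x, labels, normalize = TRUE) {
  stopifnot(inherits(forest, "urf_forest"))
  x <- check_feature_matrix(x, min_n = 1L)
  if (inherits(labels, "urf_clusters")) labels <- labels$labels
  labels <- as.integer(labels)
  n <- nrow(x)
  stopifnot(length(labels) == n)
  clusters <- sort(unique(labels))
  if (any(tabulate(factor(labels, levels = clusters)) < 1L))
    stop("every cluster must contain at least one sample")
  k <- length(clusters)
  p <- forest$p
  gini <- function(pr) 2 * pr * (1 - pr)
  scores <- matrix(0, k, p,
                   dimnames = list(paste0("cluster", clusters),
                                   forest$feature_names))
  bin <- sapply(clusters, function(c) labels == c)  # n x k logical
  for (tree in forest$trees) {
    walk <- function(node, idx) {
      f <- tree$feature[node]
      if (is.na(f)) return(invisible())
      go_left <- x[idx, f] <= tree$threshold[node]
      li <- idx[go_left]; ri <- idx[!go_left]
      nT <- length(idx); nL <- length(li); nR <- length(ri)
      if (nT > 0L && nL > 0L && nR > 0L) {
        pT <- colMeans(bin[idx, , drop = FALSE])
        pL <- colMeans(bin[li, , drop = FALSE])
        pR <- colMeans(bin[ri, , drop = FALSE])
        dec <- gini(pT) - (nL * gini(pL) + nR * gini(pR)) / nT
        scores[, f] <<- scores[, f] + (nT / n) * dec
      }
      walk(tree$left[node], li)
      walk(tree$right[node], ri)
    }
    walk(1L, seq_len(n))
  }
  scores <- scores / length(forest$trees)
  scores[scores < 0] <- 0  # floating-point guard; Gini decrease is >= 0
  raw <- scores
  if (normalize) {
    rs <- rowSums(scores)
    scores[rs > 0, ] <- scores[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  structure(scores, raw = raw, clusters = clusters,
            class = c("urf_importance", "matrix", "array"))
}

#' Pearson correlation of importance profiles between clusters
#'
#' Correlates the p-dimensional importance vectors of every cluster pair.
#' High correlation means two clusters are distinguished by the same
#' features; near-zero correlation marks clusters driven by disjoint sets of
#' features. A cluster whose scores have zero variance yields `NA` against
#' every other cluster.
#'
#' @param importance an `urf_importance` matrix from [cluster_importance()].
#' @return symmetric k-by-k correlation matrix with unit diagonal.
#' @export
importance_correlation <- function(importance) {
  stopifnot(is.matrix(importance))
  if (nrow(importance) < 2L) stop("need at least two clusters")
  v <- apply(importance, 1, sd)
  if (any(v == 0))
    warning("zero-variance importance vector(s): ",
            paste(rownames(importance)[v == 0], collapse = ", "),
            "; correlations reported as NA")
  r <- suppressWarnings(cor(t(unclass(importance))))
  diag(r) <- 1
  r
}

#' @export
print.urf_importance <- function(x, digits = 3, ...) {
  cat(sprintf("Cluster-specific feature importance (%d clusters x %d features)\n",
              nrow(x), ncol(x)))
  m <- unclass(x)
  attributes(m)[c("raw", "clusters")] <- NULL
  print(round(m, digits))
  invisible(x)
}
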