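#' Convert an affinity matrix to a distance matrix
#'
#' `D = 1 - A`: the simplest monotone map from affinities in \eqn{[0, 1]} to
#' distances with a zero diagonal.
#'
#' @param a symmetric affinity matrix with entries in \eqn{[0, 1]}.
#' @return symmetric distance matrix with zero diagonal.
#' @export
affinity_to_distance <- function(a) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  if (min(a) < 0 || max(a) > 1) stop("affinities must lie in [0, 1]")
  d <- 1 - unclass(a)
  diag(d) <- 0
  d
}

#' Ward clustering of a precomputed distance matrix
#'
#' Agglomerative Ward clustering of the supplied distances
#' ([stats::hclust()] method `"ward.D2"`, the Lance-Williams update that
#' implements Ward's minimum-variance criterion for a distance input), with
#' the dendrogram cut to exactly `k` clusters.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param k number of clusters, `2 <= k <= n`.
#' @return a list of class `urf_clusters`: `labels` (integer vector named by
#'   sample IDs, values `1..k`), `k`, and `hclust` (the full merge history).
#' @export
ward_cluster <- function(d, k) {
  dd <- if (inherits(d, "dist")) d else as.dist(d)
  n <- attr(dd, "Size")
  k <- as.integer(k)
  if (k < 1L || k > n) stop("'k' must be between 1 and the number of samples")
  hc <- hclust(dd, method = "ward.D2")
  structure(list(labels = cutree(hc, k = k), k = k, hclust = hc),
            class = "urf_clusters")
}

#' @export
print.urf_clusters <- function(x, ...) {
  cat(sprintf("Ward clustering: %d clusters over %d samples\n",
              x$k, length(x$labels)))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Mean silhouette width of a partition on a distance matrix
#'
#' For sample i with cluster C(i): `a(i)` is the mean distance to the other
#' members of C(i), `b(i)` the smallest mean distance to any other cluster,
#' and `s(i) = (b - a) / max(a, b)`; singletons score 0. Returns the mean of
#' `s(i)` over all samples.
#'
#' @param d symmetric distance matrix.
#' @param labels integer cluster labels, one per sample.
#' @return mean silhouette width in \eqn{[-1, 1]}.
#' @export
silhouette_score <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(length(labels) == n)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop("need at least two clusters for a silhouette")
  sizes <- tabulate(labels, k)
  # n x k matrix of summed distances from each sample to each cluster
  sums <- sapply(seq_len(k), function(c) rowSums(d[, labels == c, drop = FALSE]))
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- labels[i]
    if (sizes[ci] == 1L) { s[i] <- 0; next }
    a <- sums[i, ci] / (sizes[ci] - 1L)
    b <- min(sums[i, -ci] / sizes[-ci])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Select the number of clusters by silhouette
#'
#' Cuts the Ward dendrogram at each candidate `k` and returns the one
#' maximizing the mean silhouette width on `d`; ties go to the smallest `k`.
#'
#' @param d symmetric distance matrix.
#' @param k_range candidate values, a subset of `2:(n - 1)`.
#' @return the selected `k`, with the per-k silhouette widths attached as
#'   attribute `"widths"`.
#' @export
silhouette_select_k <- function(d, k_range = 2:7) {
  d <- as.matrix(d)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L) stop("'k_range' is empty")
  stopifnot(min(k_range) >= 2L, max(k_range) <= nrow(d) - 1L)
  hc <- hclust(as.dist(d), method = "ward.D2")
  w <- vapply(k_range,
              function(k) silhouette_score(d, cutree(hc, k = k)),
              numeric(1))
  structure(k_range[which.max(w)], widths = setNames(w, k_range))
}
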