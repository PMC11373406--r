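test_that("single-leaf forests carry zero importance", {
  x <- matrix(rep(2, 20), 20, 1, dimnames = list(paste0("s", 1:20), "f"))
  f <- urf_fit(x, n_trees = 3, mtry = 1, seed = 1)
  imp <- cluster_importance(f, x, rep(1:2, 10), normalize = FALSE)
  expect_true(all(imp == 0))
})

test_that("a feature that separates the clusters takes all the mass", {
  d <- two_blobs_1d(n_per = 15)
  f <- urf_fit(d$x, n_trees = 20, mtry = 1, seed = 3)
  imp <- cluster_importance(f, d$x, d$labels)
  expect_equal(unname(rowSums(imp)), c(1, 1))
  expect_true(all(imp[, 1] == 1))
})

test_that("cluster-specific importance localizes to the separating feature", {
  d <- crossed_blobs_2d()
  f <- urf_fit(d$x, n_trees = 60, mtry = 1, min_leaf_size = 5, seed = 13)
  imp <- cluster_importance(f, d$x, d$labels)
  # cluster 1 sits apart in feature 1, cluster 2 in feature 2
  expect_gt(imp["cluster1", "f1"], imp["cluster1", "f2"])
  expect_gt(imp["cluster2", "f2"], imp["cluster2", "f1"])
})

test_that("unnormalized importance conserves the total impurity decrease", {
  d <- crossed_blobs_2d(n_per = 10)
  f <- urf_fit(d$x, n_trees = 8, mtry = 2, min_leaf_size = 3, seed = 29)
  imp <- cluster_importance(f, d$x, d$labels, normalize = FALSE)
  # independent recomputation of per-cluster totals by walking each tree
  gini <- function(p) 2 * p * (1 - p)
  n <- nrow(d$x)
  totals <- rep(0, 3)
  for (tree in f$trees) {
    recurse <- function(node, idx) {
      if (is.na(tree$feature[node])) return(invisible())
      go <- d$x[idx, tree$feature[node]] <= tree$threshold[node]
      li <- idx[go]; ri <- idx[!go]
      for (c in 1:3) {
        pT <- mean(d$labels[idx] == c)
        pL <- mean(d$labels[li] == c); pR <- mean(d$labels[ri] == c)
        dec <- gini(pT) - (length(li) * gini(pL) + length(ri) * gini(pR)) /
          length(idx)
        totals[c] <<- totals[c] + length(idx) / n * dec
      }
      recurse(tree$left[node], li); recurse(tree$right[node], ri)
    }
    recurse(1L, seq_len(n))
  }
  expect_equal(unname(rowSums(imp)), totals / length(f$trees),
               tolerance = 1e-10)
})

test_that("importance is equivariant under cluster relabeling", {
  d <- crossed_blobs_2d(n_per = 10)
  f <- urf_fit(d$x, n_trees = 10, mtry = 1, seed = 41)
  imp1 <- cluster_importance(f, d$x, d$labels)
  relab <- c(3L, 1L, 2L)[d$labels]
  imp2 <- cluster_importance(f, d$x, relab)
  expect_equal(unclass(imp1["cluster2", ]), unclass(imp2["cluster1", ]))
  expect_equal(unclass(imp1["cluster1", ]), unclass(imp2["cluster3", ]))
})

test_that("features never used in a split score exactly zero", {
  # feature 2 is constant: no split can use it
  set.seed(55)
  x <- cbind(f1 = c(rnorm(10, 0), rnorm(10, 8)), f2 = rep(1, 20))
  rownames(x) <- paste0("s", 1:20)
  f <- urf_fit(x, n_trees = 10, mtry = 2, seed = 56)
  imp <- cluster_importance(f, x, rep(1:2, each = 10), normalize = FALSE)
  expect_true(all(imp[, "f2"] == 0))
  expect_true(any(imp[, "f1"] > 0))
})

test_that("empty clusters and label length mismatches are rejected", {
  d <- two_blobs_1d()
  f <- urf_fit(d$x, n_trees = 3, mtry = 1, seed = 6)
  expect_error(cluster_importance(f, d$x, d$labels[-1]), "length|labels")
})

test_that("importance correlations follow the Pearson algebra", {
  imp <- structure(rbind(c(1, 2, 3, 4), c(1, 2, 3, 4)),
                   class = c("urf_importance", "matrix", "array"))
  rownames(imp) <- c("cluster1", "cluster2")
  expect_equal(importance_correlation(imp)["cluster1", "cluster2"], 1)
  # orthogonal one-hot rows: r = -1/(p-1)
  p <- 12
  oh <- structure(rbind(c(1, rep(0, p - 1)), c(0, 1, rep(0, p - 2))),
                  class = c("urf_importance", "matrix", "array"))
  rownames(oh) <- c("cluster1", "cluster2")
  expect_equal(importance_correlation(oh)["cluster1", "cluster2"],
               -1 / (p - 1))
  # hand-computed textbook case: x = (1,2,3,4), y = (1,3,2,4) => r = 0.8
  tb <- structure(rbind(c(1, 2, 3, 4), c(1, 3, 2, 4)),
                  class = c("urf_importance", "matrix", "array"))
  rownames(tb) <- c("cluster1", "cluster2")
  expect_equal(importance_correlation(tb)["cluster1", "cluster2"], 0.8)
})

test_that("zero-variance importance vectors yield NA correlations with a warning", {
  imp <- structure(rbind(c(0.5, 0.5, 0), c(0, 0.5, 0.5), c(1, 1, 1) / 3),
                   class = c("urf_importance", "matrix", "array"))
  rownames(imp) <- paste0("cluster", 1:3)
  expect_warning(r <- importance_correlation(imp), "zero-variance")
  expect_true(is.na(r["cluster3", "cluster1"]))
  expect_false(is.na(r["cluster1", "cluster2"]))
  expect_equal(diag(r), rep(1, 3), ignore_attr = TRUE)
})
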