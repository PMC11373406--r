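test_that("tree co-occurrence equals the same-leaf indicator", {
  d <- crossed_blobs_2d()
  f <- urf_fit(d$x, n_trees = 5, mtry = 1, seed = 21)
  for (tree in f$trees) {
    cc <- tree_cooccurrence(tree, d$x)
    l <- assign_leaves(tree, d$x)
    expect_identical(unname(cc), unname(outer(l, l, function(a, b)
      as.integer(a == b))))
    expect_true(isSymmetric(cc))
    expect_true(all(diag(cc) == 1L))
  }
})

test_that("forest counts sum tree indicators; diagonal equals the tree count", {
  d <- two_blobs_1d()
  f <- urf_fit(d$x, n_trees = 12, mtry = 1, seed = 5)
  counts <- forest_counts(f, d$x)
  manual <- Reduce(`+`, lapply(f$trees, tree_cooccurrence, x = d$x))
  expect_equal(unclass(counts), unclass(manual), ignore_attr = TRUE)
  expect_true(all(diag(counts) == 12L))
  expect_true(all(counts <= 12L))
  expect_true(isSymmetric(unclass(counts)))
})

test_that("affinity normalization divides by the maximal entry", {
  expect_equal(unclass(normalize_affinity(matrix(c(5, 2, 2, 5), 2))),
               matrix(c(1, 0.4, 0.4, 1), 2))
  set.seed(3)
  c0 <- matrix(sample(0:9, 25, TRUE), 5); c0 <- c0 + t(c0); diag(c0) <- 20
  expect_equal(max(normalize_affinity(c0)), 1)
  expect_equal(unclass(normalize_affinity(3L * c0)),
               unclass(normalize_affinity(c0)))
  expect_error(normalize_affinity(matrix(0, 3, 3)), "all zero")
})

test_that("affinity invariants hold end-to-end", {
  d <- crossed_blobs_2d()
  a <- urf_affinity(d$x, n_trees = 40, mtry = 1, seed = 8)
  expect_true(isSymmetric(unclass(a)))
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(unname(diag(a)), rep(1, nrow(a)))
  expect_equal(max(a), 1)
})

test_that("multi-omics fusion sums raw counts over layers", {
  d <- crossed_blobs_2d()
  f1 <- urf_fit(d$x, n_trees = 7, mtry = 1, seed = 1)
  f2 <- urf_fit(d$x * 2, n_trees = 7, mtry = 1, seed = 2)
  # single layer: identical to forest_counts
  expect_equal(unclass(multiomics_counts(list(f1), list(d$x))),
               unclass(forest_counts(f1, d$x)), ignore_attr = TRUE)
  # two layers: element-wise sum
  fused <- multiomics_counts(list(f1, f2), list(d$x, d$x * 2))
  expect_equal(unclass(fused),
               unclass(forest_counts(f1, d$x)) +
                 unclass(forest_counts(f2, d$x * 2)), ignore_attr = TRUE)
  # fusing a layer with itself leaves the affinity unchanged
  a1 <- normalize_affinity(forest_counts(f1, d$x))
  a2 <- normalize_affinity(multiomics_counts(list(f1, f1), list(d$x, d$x)))
  expect_equal(unclass(a1), unclass(a2))
})

test_that("fused counts on a 4-sample toy equal the hand-computed sum", {
  # layer 1 separates {s1,s2} from {s3,s4}; layer 2 separates {s1,s3} from {s2,s4}
  x1 <- matrix(c(0, 0, 10, 10), 4, 1, dimnames = list(paste0("s", 1:4), "f"))
  x2 <- matrix(c(0, 10, 0, 10), 4, 1, dimnames = list(paste0("s", 1:4), "f"))
  f1 <- urf_fit(x1, n_trees = 1, mtry = 1, min_leaf_size = 2,
                bootstrap = FALSE, seed = 1)
  f2 <- urf_fit(x2, n_trees = 1, mtry = 1, min_leaf_size = 2,
                bootstrap = FALSE, seed = 1)
  fused <- multiomics_counts(list(f1, f2), list(x1, x2))
  hand <- matrix(c(2, 1, 1, 0,
                   1, 2, 0, 1,
                   1, 0, 2, 1,
                   0, 1, 1, 2), 4, byrow = TRUE)
  expect_equal(unclass(fused), hand, ignore_attr = TRUE)
})

test_that("sample-ID mismatches across layers are rejected with the layer named", {
  d <- crossed_blobs_2d()
  f <- urf_fit(d$x, n_trees = 3, mtry = 1, seed = 1)
  x_bad <- d$x[rev(seq_len(nrow(d$x))), ]
  expect_error(multiomics_counts(list(f, f), list(d$x, x_bad)), "layer 2")
})

test_that("within-cluster affinity exceeds between-cluster affinity on tight blobs", {
  d <- make_equal_globular(sd = 0.1, seed = 19)
  a <- urf_affinity(d$x, n_trees = 100, mtry = 1, seed = 23)
  same <- outer(d$labels, d$labels, "==")
  up <- upper.tri(a)
  expect_gt(mean(a[same & up]), mean(a[!same & up]) * 5)
})
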