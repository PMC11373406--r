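test_that("equal-globular clusters sit at the stated centers", {
  d <- make_equal_globular(sd = 0.1, seed = 1)
  expect_equal(dim(d$x), c(300L, 2L))
  expect_equal(unname(table(d$labels)), rep(100L, 3), ignore_attr = TRUE)
  centers <- rbind(c(1, 0), c(0, 1), c(1, 1))
  for (c in 1:3) {
    mu <- colMeans(d$x[d$labels == c, ])
    expect_true(all(abs(mu - centers[c, ]) < 3 * 0.1 / sqrt(100)))
  }
  expect_identical(make_equal_globular(0.1, seed = 1)$x, d$x)
  expect_false(identical(make_equal_globular(0.1, seed = 2)$x, d$x))
  expect_error(make_equal_globular(0), "positive")
})

test_that("outlier scenario adds the stated percentage with inherited labels", {
  d <- make_outlier_scenario(10, seed = 2)
  expect_equal(nrow(d$x), 330L)
  expect_equal(unname(table(d$labels)), rep(110L, 3), ignore_attr = TRUE)
  d0 <- make_outlier_scenario(0, seed = 3)
  expect_equal(nrow(d0$x), 300L)
  # outliers concentrate near their wide centers
  d_big <- make_outlier_scenario(10, seed = 4, n_per_cluster = 2000)
  outs <- d_big$x[6001:6200, ]  # first outlier block, center (3, 0), sd 1
  expect_true(all(abs(colMeans(outs) - c(3, 0)) < 3 / sqrt(200)))
  expect_error(make_outlier_scenario(-1), ">= 0")
})

test_that("varying-size clusters follow the sd schedule 0.1, 0.1+0.1m, 0.1+0.2m", {
  d <- make_varying_sizes(3, seed = 5, n_per_cluster = 4000)
  sds <- sapply(1:3, function(c) mean(apply(d$x[d$labels == c, ], 2, sd)))
  expect_equal(sds, c(0.1, 0.4, 0.7), tolerance = 0.02)
  expect_equal(nrow(make_varying_sizes(1, seed = 1)$x), 300L)
})

test_that("ring radii respect the bounds and the radial gap", {
  d <- make_rings(2, seed = 6)
  r <- sqrt(rowSums(d$x^2))
  expect_true(all(r[d$labels == 1] >= 1 & r[d$labels == 1] <= 2))
  expect_true(all(r[d$labels == 2] >= 4 & r[d$labels == 2] <= 5))
  expect_gt(min(r[d$labels == 2]) - max(r[d$labels == 1]), 0)
  expect_identical(make_rings(2, seed = 6)$x, d$x)
  expect_error(make_rings(0), "positive")
})

test_that("half moons produce two interleaved shapes", {
  d <- make_half_moons(0.05, seed = 7)
  expect_equal(dim(d$x), c(200L, 2L))
  expect_equal(unname(table(d$labels)), rep(100L, 2), ignore_attr = TRUE)
})

test_that("ARI matches its definition on frozen cases", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  # contingency [[2,0],[1,1]]: hand evaluation of the formula gives 0
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 1, 2)), 0)
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
})

test_that("ARI equals brute-force pair counting and the mclust reference", {
  set.seed(8)
  for (case in 1:200) {
    n <- sample(3:8, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), brute_ari(a, b),
                 tolerance = 1e-12)
  }
  a <- sample(1:4, 60, replace = TRUE)
  b <- ifelse(runif(60) < 0.3, sample(1:4, 60, replace = TRUE), a)
  expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
               tolerance = 1e-12)
})

test_that("scenario experiments produce the full design grid deterministically", {
  res <- run_scenario_experiment("rings", parameters = 2, n_replicates = 2,
                                 seed = 9, n_trees = 20)
  expect_equal(nrow(res), 2L * 3L)
  expect_setequal(unique(res$method), c("uRF", "HC", "HCscaled"))
  expect_true(all(res$ari >= -1 & res$ari <= 1))
  res2 <- run_scenario_experiment("rings", parameters = 2, n_replicates = 2,
                                  seed = 9, n_trees = 20)
  expect_identical(res, res2)
  # Euclidean methods need no forest and are fast across a grid
  res3 <- run_scenario_experiment("outliers", parameters = c(2, 10),
                                  n_replicates = 2, seed = 10, methods = "HC")
  expect_equal(nrow(res3), 4L)
})
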