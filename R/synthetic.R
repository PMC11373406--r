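# Two-dimensional benchmark scenario generators. Each returns
# list(x = n x 2 matrix, labels = integer ground truth, scenario, parameter)
# and is a pure function of (parameters, seed).

scenario_dataset <- function(x, labels, scenario, parameter) {
  rownames(x) <- paste0("s", seq_len(nrow(x)))
  colnames(x) <- c("x", "y")
  list(x = x, labels = as.integer(labels),
       scenario = scenario, parameter = parameter)
}

#' Three equal globular clusters
#'
#' 100 points per cluster (by default) drawn from isotropic Gaussians at
#' centers (1, 0), (0, 1) and (1, 1); the shared standard deviation controls
#' the degree of separation (0.1 well separated, 0.5 heavily overlapping).
#'
#' @param sd positive standard deviation of every cluster.
#' @param seed optional integer seed.
#' @param n_per_cluster points per cluster.
#' @return list with `x` (n-by-2 matrix), `labels`, `scenario`, `parameter`.
#' @export
make_equal_globular <- function(sd = 0.25, seed = NULL, n_per_cluster = 100L) {
  if (sd <= 0) stop("'sd' must be positive")
  centers <- rbind(c(1, 0), c(0, 1), c(1, 1))
  with_seed(seed, {
    x <- do.call(rbind, lapply(1:3, function(c)
      cbind(rnorm(n_per_cluster, centers[c, 1], sd),
            rnorm(n_per_cluster, centers[c, 2], sd))))
    scenario_dataset(x, rep(1:3, each = n_per_cluster), "equal_globular", sd)
  })
}

#' Three globular clusters with outliers
#'
#' Core clusters as in [make_equal_globular()] with sd 0.25; an additional
#' `outlier_pct` percent of the core count is drawn from wide Gaussians
#' (sd 1) at (3, 0), (0, 3) and (3, 3). Each outlier carries the label of the
#' cluster its outlier center is associated with, keeping k = 3.
#'
#' @param outlier_pct percentage of outliers (e.g. 10 adds 30 points to 300).
#' @param seed optional integer seed.
#' @param n_per_cluster core points per cluster.
#' @param sd core cluster standard deviation.
#' @return list with `x`, `labels`, `scenario`, `parameter`.
#' @export
make_outlier_scenario <- function(outlier_pct, seed = NULL,
                                  n_per_cluster = 100L, sd = 0.25) {
  if (outlier_pct < 0) stop("'outlier_pct' must be >= 0")
  centers <- rbind(c(1, 0), c(0, 1), c(1, 1))
  out_centers <- rbind(c(3, 0), c(0, 3), c(3, 3))
  n_out_total <- round(outlier_pct / 100 * 3 * n_per_cluster)
  n_out <- tabulate(rep_len(1:3, n_out_total), 3L)
  with_seed(seed, {
    core <- do.call(rbind, lapply(1:3, function(c)
      cbind(rnorm(n_per_cluster, centers[c, 1], sd),
            rnorm(n_per_cluster, centers[c, 2], sd))))
    outs <- do.call(rbind, lapply(1:3, function(c)
      if (n_out[c] == 0) NULL else
      cbind(rnorm(n_out[c], out_centers[c, 1], 1),
            rnorm(n_out[c], out_centers[c, 2], 1))))
    x <- rbind(core, outs)
    labels <- c(rep(1:3, each = n_per_cluster), rep(1:3, times = n_out))
    scenario_dataset(x, labels, "outliers", outlier_pct)
  })
}

#' Three globular clusters of varying size
#'
#' Clusters at (0, 0), (1, 1) and (-2, 2) with standard deviations 0.1,
#' 0.1 + 0.1 m and 0.1 + 0.2 m: increasing `m` both widens the second and
#' third clusters and increases their overlap (m = 3 gives sds 0.1, 0.4,
#' 0.7).
#'
#' @param m spread multiplier, typically 1 to 5.
#' @param seed optional integer seed.
#' @param n_per_cluster points per cluster.
#' @return list with `x`, `labels`, `scenario`, `parameter`.
#' @export
make_varying_sizes <- function(m, seed = NULL, n_per_cluster = 100L) {
  if (m < 0) stop("'m' must be >= 0")
  centers <- rbind(c(0, 0), c(1, 1), c(-2, 2))
  sds <- c(0.1, 0.1 + m * 0.1, 0.1 + m * 0.2)
  with_seed(seed, {
    x <- do.call(rbind, lapply(1:3, function(c)
      cbind(rnorm(n_per_cluster, centers[c, 1], sds[c]),
            rnorm(n_per_cluster, centers[c, 2], sds[c]))))
    scenario_dataset(x, rep(1:3, each = n_per_cluster), "varying_sizes", m)
  })
}

#' Two concentric rings
#'
#' Non-globular benchmark: ring 1 has radii uniform in \[1, 2\]; ring 2, also
#' of width 1, starts `distance` beyond ring 1's outer radius (radii uniform
#' in \[2 + distance, 3 + distance\]). Angles are uniform.
#'
#' @param distance radial gap between the rings, typically 1 to 3.
#' @param seed optional integer seed.
#' @param n_per_ring points per ring.
#' @return list with `x`, `labels`, `scenario`, `parameter`.
#' @export
make_rings <- function(distance, seed = NULL, n_per_ring = 100L) {
  if (distance <= 0) stop("'distance' must be positive")
  with_seed(seed, {
    r <- c(runif(n_per_ring, 1, 2),
           runif(n_per_ring, 2 + distance, 3 + distance))
    th <- runif(2 * n_per_ring, 0, 2 * pi)
    x <- cbind(r * cos(th), r * sin(th))
    scenario_dataset(x, rep(1:2, each = n_per_ring), "rings", distance)
  })
}

#' Two interleaved half moons
#'
#' Additional non-convex benchmark shape; not used by the headline
#' experiments but convenient for exploration.
#'
#' @param noise Gaussian noise standard deviation.
#' @param seed optional integer seed.
#' @param n_per_moon points per moon.
#' @return list with `x`, `labels`, `scenario`, `parameter`.
#' @export
make_half_moons <- function(noise = 0.05, seed = NULL, n_per_moon = 100L) {
  if (noise < 0) stop("'noise' must be >= 0")
  with_seed(seed, {
    t1 <- runif(n_per_moon, 0, pi)
    t2 <- runif(n_per_moon, 0, pi)
    x <- rbind(cbind(cos(t1), sin(t1)),
               cbind(1 - cos(t2), 0.5 - sin(t2)))
    x <- x + matrix(rnorm(length(x), 0, noise), ncol = 2)
    scenario_dataset(x, rep(1:2, each = n_per_moon), "half_moons", noise)
  })
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement computed from the contingency table: 1 for
#' partitions identical up to label permutation, about 0 for independent
#' ones.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a number in \eqn{[-1, 1]}.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  if (length(a) < 2L) stop("need at least two samples")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(length(a))
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}

#' Replicated scenario experiment: uRF vs Euclidean Ward clustering
#'
#' For every parameter value and replicate, generates a dataset, builds three
#' distance matrices — the unsupervised-forest affinity converted to a
#' distance (`uRF`), plain Euclidean distance (`HC`), and Euclidean distance
#' after per-feature standardization (`HCscaled`) — cuts a Ward dendrogram at
#' the true number of clusters, and records the Adjusted Rand Index against
#' the ground truth.
#'
#' @param scenario one of `"equal_globular"`, `"outliers"`,
#'   `"varying_sizes"`, `"rings"`, `"half_moons"`.
#' @param parameters scenario parameter grid; defaults to the scenario's
#'   standard grid (sd 0.1-0.5; outlier percentage 2-10; m 1-5; ring
#'   distance 1-3).
#' @param n_replicates independently generated datasets per parameter value.
#' @param seed master seed; every dataset and forest gets a derived seed.
#' @param n_trees,mtry,min_leaf_size forest parameters (defaults are the
#'   two-dimensional benchmark settings).
#' @param methods subset of `c("uRF", "HC", "HCscaled")`.
#' @return data.frame with columns `scenario`, `parameter`, `method`,
#'   `replicate`, `ari`.
#' @export
run_scenario_experiment <- function(scenario, parameters = NULL,
                                    n_replicates = 30L, seed = 1L,
                                    n_trees = 500L, mtry = 1L,
                                    min_leaf_size = 5L,
                                    methods = c("uRF", "HC", "HCscaled")) {
  scenario <- match.arg(scenario, c("equal_globular", "outliers",
                                    "varying_sizes", "rings", "half_moons"))
  gen <- switch(scenario,
    equal_globular = make_equal_globular,
    outliers = make_outlier_scenario,
    varying_sizes = make_varying_sizes,
    rings = make_rings,
    half_moons = make_half_moons)
  if (is.null(parameters))
    parameters <- switch(scenario,
      equal_globular = seq(0.1, 0.5, 0.1),
      outliers = c(2, 4, 6, 8, 10),
      varying_sizes = 1:5,
      rings = seq(1, 3, 0.5),
      half_moons = c(0.05, 0.1))
  methods <- match.arg(methods, several.ok = TRUE)
  true_k <- if (scenario %in% c("rings", "half_moons")) 2L else 3L
  n_cells <- length(parameters) * n_replicates
  seeds <- matrix(derive_seeds(seed, 2L * n_cells), ncol = 2L)
  out <- vector("list", n_cells * length(methods))
  cell <- 0L
  row <- 0L
  for (param in parameters) {
    for (rep in seq_len(n_replicates)) {
      cell <- cell + 1L
      ds <- gen(param, seed = seeds[cell, 1])
      for (method in methods) {
        d <- switch(method,
          uRF = affinity_to_distance(urf_affinity(
            ds$x, n_trees = n_trees, mtry = mtry,
            min_leaf_size = min_leaf_size, seed = seeds[cell, 2])),
          HC = as.matrix(dist(ds$x)),
          HCscaled = as.matrix(dist(scale(ds$x))))
        ari <- adjusted_rand_index(ward_cluster(d, true_k)$labels, ds$labels)
        row <- row + 1L
        out[[row]] <- data.frame(scenario = scenario, parameter = param,
                                 method = method, replicate = rep, ari = ari)
      }
    }
  }
  do.call(rbind, out[seq_len(row)])
}
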