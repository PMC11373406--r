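# Independent brute-force oracles used to validate the fast implementations.

# split score by literal double loops over ordered pairs
brute_delta_f <- function(x, left) {
  d_box <- function(v) {
    n <- length(v)
    if (n < 2) return(0)
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
      s <- s + (v[i] - v[j])^2
    s / (n * (n - 1))
  }
  vl <- x[left]; vr <- x[!left]
  s <- 0
  for (i in seq_along(vl)) for (j in seq_along(vr))
    s <- s + (vl[i] - vr[j])^2
  d_nabla <- s / (length(vl) * length(vr))
  if (d_nabla == 0) return(NA_real_)
  (d_box(vl) + d_box(vr)) / 2 / d_nabla
}

# adjusted Rand index by explicit pair counting
brute_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  np <- n * (n - 1) / 2
  expected <- (s11 + s10) * (s11 + s01) / np
  denom <- ((s11 + s10) + (s11 + s01)) / 2 - expected
  if (denom == 0) return(1)
  (s11 - expected) / denom
}

# naive O(n^3) agglomerative Ward on a distance matrix: the Lance-Williams
# update on squared distances with the Ward coefficients, reported on the
# distance scale. Returns merge heights and the k-cluster memberships.
brute_ward2 <- function(d, k_keep = 2:3) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  heights <- numeric(0)
  cuts <- list()
  while (length(active) > 1) {
    m <- length(active)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (d2[i, j] < best[1]) best <- c(d2[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, sqrt(best[1]))
    ni <- sizes[i]; nj <- sizes[j]
    newd2 <- sapply(seq_len(m), function(l) {
      if (l == i || l == j) return(NA_real_)
      nl <- sizes[l]
      ((ni + nl) * d2[i, l] + (nj + nl) * d2[j, l] - nl * d2[i, j]) /
        (ni + nj + nl)
    })
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d2[keep, keep, drop = FALSE], newd2[keep]),
                c(newd2[keep], 0))
    active <- c(active[keep], list(c(active[[i]], active[[j]])))
    sizes <- c(sizes[keep], ni + nj)
    if (length(active) %in% k_keep) {
      lab <- integer(n)
      for (c in seq_along(active)) lab[active[[c]]] <- c
      cuts[[as.character(length(active))]] <- lab
    }
  }
  list(heights = heights, cuts = cuts)
}

# per-sample silhouette by explicit loops
brute_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(d[i, labels == cl]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# small deterministic fixtures
two_blobs_1d <- function(n_per = 10, gap = 10, seed = 42) {
  set.seed(seed)
  x <- matrix(c(rnorm(n_per, 0, 0.5), rnorm(n_per, gap, 0.5)), ncol = 1)
  rownames(x) <- paste0("s", seq_len(2 * n_per))
  colnames(x) <- "f1"
  list(x = x, labels = rep(1:2, each = n_per))
}

crossed_blobs_2d <- function(n_per = 20, seed = 7) {
  # feature 1 separates cluster A from the rest, feature 2 cluster B
  set.seed(seed)
  x <- rbind(
    cbind(rnorm(n_per, 8, 0.3), rnorm(n_per, 0, 0.3)),   # A: extreme in f1
    cbind(rnorm(n_per, 0, 0.3), rnorm(n_per, 8, 0.3)),   # B: extreme in f2
    cbind(rnorm(n_per, 0, 0.3), rnorm(n_per, 0, 0.3)))   # C: baseline
  rownames(x) <- paste0("s", seq_len(3 * n_per))
  colnames(x) <- c("f1", "f2")
  list(x = x, labels = rep(1:3, each = n_per))
}
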