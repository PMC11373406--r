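#' Concatenate client forests into a federated global model
#'
#' The federated global model is simply the ordered concatenation of every
#' client's locally grown trees, tagged with their client of origin. No tree
#' is modified and no sample data is involved: clients exchange serialized
#' trees only (see [write_urf_model()]).
#'
#' @param models list of `urf_forest` objects, one per client, all fitted on
#'   the same feature schema.
#' @param client_ids optional character vector naming the clients; defaults
#'   to `names(models)` or `client1, client2, ...`.
#' @return an object of class `urf_federated` with elements `trees`,
#'   `client_ids` (one per tree), `client_tree_counts`, `p`,
#'   `feature_names` and `params` (the first client's, kept for reference).
#' @export
concatenate_models <- function(models, client_ids = NULL) {
  stopifnot(is.list(models), length(models) >= 1L)
  lapply(models, function(m) stopifnot(inherits(m, "urf_forest")))
  if (is.null(client_ids)) {
    client_ids <- names(models)
    if (is.null(client_ids))
      client_ids <- paste0("client", seq_along(models))
  }
  stopifnot(length(client_ids) == length(models))
  ref <- models[[1]]$feature_names
  for (k in seq_along(models)) {
    if (!identical(models[[k]]$feature_names, ref) ||
        models[[k]]$p != models[[1]]$p)
      stop("feature schema of client '", client_ids[k],
           "' differs from client '", client_ids[1], "'")
  }
  n_k <- vapply(models, function(m) length(m$trees), integer(1))
  structure(list(
    trees = do.call(c, lapply(models, `[[`, "trees")),
    client_ids = rep(client_ids, times = n_k),
    client_tree_counts = setNames(n_k, client_ids),
    p = models[[1]]$p,
    feature_names = ref,
    params = models[[1]]$params
  ), class = "urf_federated")
}

#' @export
print.urf_federated <- function(x, ...) {
  cat("Federated unsupervised random forest (global model)\n")
  cat(sprintf("  clients: %d  total trees: %d\n",
              length(x$client_tree_counts), length(x$trees)))
  cat("  trees per client:",
      paste(sprintf("%s=%d", names(x$client_tree_counts),
                    x$client_tree_counts), collapse = ", "), "\n")
  invisible(x)
}

#' Federated affinity for one client's samples
#'
#' Propagates a client's own samples through the global model (every tree of
#' every client) and normalizes the summed leaf co-occurrence counts by their
#' maximal entry. The result is `n_local`-by-`n_local`: only a client's own
#' sample pairs are ever compared, so no raw data crosses client boundaries.
#'
#' @param model an `urf_federated` global model.
#' @param x_local the client's sample-by-feature matrix on the shared schema.
#' @return an `urf_affinity` matrix over the client's samples.
#' @export
federated_affinity <- function(model, x_local) {
  stopifnot(inherits(model, "urf_federated"))
  normalize_affinity(forest_counts(model, x_local))
}

#' Simulate a federated run on one dataset
#'
#' Partitions the rows of `x` uniformly at random across `n_clients` clients,
#' fits a local forest per client, concatenates the locals into a global
#' model, and computes for each client both the local affinity/clustering
#' (its own forest) and the federated one (its samples through the global
#' model), for side-by-side comparison.
#'
#' @param x sample-by-feature matrix.
#' @param n_clients number of simulated clients.
#' @param n_trees,mtry,min_leaf_size,bootstrap per-client forest parameters,
#'   as in [urf_fit()].
#' @param k number of clusters; an integer fixes k for every cut, `NULL`
#'   selects k per affinity by silhouette over `k_range`.
#' @param k_range candidate cluster numbers for silhouette selection.
#' @param seed integer seed controlling the partition and every forest.
#' @return a list with `global_model`, `partition` (client id per row of
#'   `x`), and `clients`: per client a list with `indices`, `local_affinity`,
#'   `local_labels`, `local_k`, `global_affinity`, `global_labels`,
#'   `global_k`.
#' @export
simulate_federation <- function(x, n_clients, n_trees = 500L, mtry = 1L,
                                min_leaf_size = 5L, bootstrap = TRUE,
                                k = NULL, k_range = 2:6, seed = NULL) {
  x <- check_feature_matrix(x)
  n_clients <- as.integer(n_clients)
  stopifnot(n_clients >= 1L)
  if (nrow(x) < n_clients * 2L * min_leaf_size)
    stop("too few samples to give every client enough data for one split")
  seeds <- derive_seeds(seed, n_clients + 1L)
  part <- with_seed(seeds[1],
    sample(rep_len(seq_len(n_clients), nrow(x))))
  locals <- lapply(seq_len(n_clients), function(cl) {
    urf_fit(x[part == cl, , drop = FALSE], n_trees = n_trees, mtry = mtry,
            min_leaf_size = min_leaf_size, bootstrap = bootstrap,
            seed = seeds[cl + 1L])
  })
  global <- concatenate_models(locals)
  cluster_affinity <- function(a) {
    d <- affinity_to_distance(a)
    kk <- if (is.null(k)) silhouette_select_k(d, k_range) else as.integer(k)
    list(labels = ward_cluster(d, kk)$labels, k = kk)
  }
  clients <- lapply(seq_len(n_clients), function(cl) {
    xi <- x[part == cl, , drop = FALSE]
    la <- normalize_affinity(forest_counts(locals[[cl]], xi))
    ga <- federated_affinity(global, xi)
    lc <- cluster_affinity(la)
    gc <- cluster_affinity(ga)
    list(indices = which(part == cl),
         local_affinity = la, local_labels = lc$labels, local_k = lc$k,
         global_affinity = ga, global_labels = gc$labels, global_k = gc$k)
  })
  list(global_model = global, partition = part, clients = clients)
}
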