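# JSON model bundle. Trees are written as nested objects,
#   internal: {"feature": <0-based int>, "threshold": "<%.17g>",
#              "left": <node>, "right": <node>}
#   leaf:     {"leaf_id": <1-based int>, "n_train": <int>}
# Thresholds travel as full-precision decimal strings so a round-trip is
# bit-stable; feature indices are 0-based on the wire, 1-based inside R.
# This schema is also the federated wire format: clients exchange these
# bundles, never sample data.

tree_to_nested <- function(tree, node = 1L) {
  if (is.na(tree$feature[node])) {
    list(leaf_id = tree$leaf_id[node], n_train = tree$n_train[node])
  } else {
    list(feature = tree$feature[node] - 1L,
         threshold = sprintf("%.17g", tree$threshold[node]),
         left = tree_to_nested(tree, tree$left[node]),
         right = tree_to_nested(tree, tree$right[node]))
  }
}

nested_to_tree <- function(node) {
  acc <- new.env(parent = emptyenv())
  acc$feature <- integer(0); acc$threshold <- numeric(0)
  acc$left <- integer(0); acc$right <- integer(0)
  acc$leaf_id <- integer(0); acc$n_train <- integer(0)
  add <- function(nd) {
    i <- length(acc$feature) + 1L
    acc$feature[i] <- NA_integer_; acc$threshold[i] <- NA_real_
    acc$left[i] <- NA_integer_; acc$right[i] <- NA_integer_
    acc$leaf_id[i] <- NA_integer_; acc$n_train[i] <- NA_integer_
    if (!is.null(nd$leaf_id)) {
      acc$leaf_id[i] <- as.integer(nd$leaf_id)
      acc$n_train[i] <- as.integer(nd$n_train)
    } else {
      acc$feature[i] <- as.integer(nd$feature) + 1L
      acc$threshold[i] <- as.numeric(nd$threshold)
      acc$left[i] <- add(nd$left)
      acc$right[i] <- add(nd$right)
    }
    i
  }
  add(node)
  structure(list(feature = acc$feature, threshold = acc$threshold,
                 left = acc$left, right = acc$right,
                 leaf_id = acc$leaf_id, n_train = acc$n_train),
            class = "urf_tree")
}

#' Serialize a forest or federated model to JSON
#'
#' Writes the model bundle (parameters, feature schema, trees) in the wire
#' format exchanged between federated clients. The round-trip through
#' [read_urf_model()] reproduces the model exactly, including thresholds
#' bit-for-bit.
#'
#' @param object an `urf_forest` or `urf_federated` model.
#' @param path output path (conventionally `model.json`).
#' @return `path`, invisibly.
#' @export
write_urf_model <- function(object, path) {
  stopifnot(inherits(object, c("urf_forest", "urf_federated")))
  bundle <- list(
    schema_version = 1L,
    type = class(object)[1],
    p = object$p,
    feature_names = object$feature_names,
    params = object$params,
    trees = lapply(object$trees, tree_to_nested)
  )
  if (inherits(object, "urf_federated")) {
    bundle$client_ids <- object$client_ids
    bundle$client_tree_counts <- as.list(object$client_tree_counts)
  }
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' Deserialize a forest or federated model from JSON
#'
#' @param path path to a bundle written by [write_urf_model()].
#' @return an `urf_forest` or `urf_federated` model.
#' @export
read_urf_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  b <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(b$schema_version) || b$schema_version != 1L)
    stop("unsupported model schema in ", path)
  trees <- lapply(b$trees, nested_to_tree)
  params <- lapply(b$params, function(v) if (is.list(v)) v else v)
  obj <- list(trees = trees, params = params, p = as.integer(b$p),
              feature_names = unlist(b$feature_names))
  if (identical(b$type, "urf_federated")) {
    obj$client_ids <- unlist(b$client_ids)
    obj$client_tree_counts <- unlist(b$client_tree_counts)
    structure(obj, class = "urf_federated")
  } else {
    structure(obj, class = "urf_forest")
  }
}
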