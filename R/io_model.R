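MODEL_SCHEMA <- "phagehost-model/1"

serialize_node <- function(node) {
  if (node$type == "leaf") {
    list(type = "leaf", positive_fraction = node$positive_fraction,
         n_samples = node$n_samples, impurity = node$impurity)
  } else {
    list(type = "split", feature = node$feature, threshold = node$threshold,
         impurity = node$impurity, n_samples = node$n_samples,
         left = serialize_node(node$left), right = serialize_node(node$right))
  }
}

deserialize_node <- function(x) {
  if (is.null(x$type)) abort("malformed tree node in model file")
  if (x$type == "leaf") {
    list(type = "leaf", positive_fraction = as.numeric(x$positive_fraction),
         n_samples = as.integer(x$n_samples), impurity = as.numeric(x$impurity))
  } else {
    list(type = "split", feature = as.character(x$feature),
         threshold = as.numeric(x$threshold),
         impurity = as.numeric(x$impurity),
         n_samples = as.integer(x$n_samples),
         left = deserialize_node(x$left), right = deserialize_node(x$right))
  }
}

#' Serialize a trained model to JSON
#'
#' The model file is a single self-describing JSON document (schema-version
#' field included): the per-genus trees, the cluster database with
#' representative sequences, the variance-filter survivor columns, and the
#' full run configuration. [read_model()] restores an identical predictor.
#'
#' @param suite A trained `host_tree_suite` (>= 1 tree).
#' @param cluster_db The frozen `cluster_db` from training.
#' @param path Output path.
#' @param run_config Optional [phagehost_config()] to embed.
#' @return The path, invisibly.
#' @export
write_model <- function(suite, cluster_db, path, run_config = NULL) {
  stopifnot(inherits(suite, "host_tree_suite"),
            inherits(cluster_db, "cluster_db"))
  if (length(suite$trees) == 0) abort("no trained trees")
  doc <- list(
    schema_version = MODEL_SCHEMA,
    columns = as.list(suite$columns),
    genera = as.list(suite$genera),
    tree_config = suite$config,
    align_config = unclass(cluster_db$config),
    run_config = if (!is.null(run_config)) unclass(run_config),
    clusters = cluster_db$clusters,
    membership = cluster_db$membership,
    trees = lapply(suite$trees, serialize_node)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a model serialized by [write_model()]
#'
#' @param path Path to a model JSON file.
#' @return A list with `suite` (`host_tree_suite`), `cluster_db`
#'   (`cluster_db`), and `run_config` (a `phagehost_config` or `NULL`).
#'   A missing or mismatched schema version, or a truncated file, is an
#'   explicit error.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort(paste0("model file not found: ", path))
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    abort(paste0("failed to parse model file ", path, ": ",
                                 conditionMessage(e)))
                  })
  if (is.null(doc$schema_version) ||
      !identical(doc$schema_version, MODEL_SCHEMA)) {
    abort(paste0("model schema version mismatch: expected ", MODEL_SCHEMA,
                 ", found ", doc$schema_version %||% "<none>"))
  }
  cl <- dplyr::bind_rows(lapply(doc$clusters, function(r) {
    tibble(cluster_id = as.integer(r$cluster_id),
           representative_id = as.character(r$representative_id),
           representative_seq = as.character(r$representative_seq),
           n_members = as.integer(r$n_members),
           n_phages = as.integer(r$n_phages),
           prevalence = as.numeric(r$prevalence),
           annotation = if (is.null(r$annotation)) NA_character_ else as.character(r$annotation))
  }))
  membership <- dplyr::bind_rows(lapply(doc$membership, function(r) {
    tibble(protein_id = as.character(r$protein_id),
           cluster_id = as.integer(r$cluster_id))
  }))
  acfg <- align_config(gap_open = doc$align_config$gap_open,
                       gap_extend = doc$align_config$gap_extend)
  cluster_db <- structure(list(clusters = cl, membership = membership,
                               config = acfg), class = "cluster_db")
  trees <- lapply(doc$trees, deserialize_node)
  suite <- structure(
    list(trees = trees, columns = unlist(doc$columns),
         genera = unlist(doc$genera),
         config = list(
           min_impurity_split = as.numeric(doc$tree_config$min_impurity_split),
           balanced = isTRUE(doc$tree_config$balanced))),
    class = "host_tree_suite"
  )
  run_config <- if (!is.null(doc$run_config)) config_from_list(doc$run_config)
  list(suite = suite, cluster_db = cluster_db, run_config = run_config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
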