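#' Run the full training-and-evaluation pipeline
#'
#' Orchestrates the whole method on a labelled corpus: select the most
#' phage-rich genera, split the corpus, call genes, cluster the training
#' proteins into families, build and filter the feature matrix, train one
#' tree per genus, vectorize the held-out phages against the frozen cluster
#' database, and score the predictions per genus.
#'
#' @param genomes Genome tibble ([read_genomes()]).
#' @param labels Host label tibble ([read_host_table()]).
#' @param config A [phagehost_config()]; `config$seed` drives the split.
#' @param proteins Optional externally predicted proteins (tibble
#'   `protein_id`, `genome_id`, `aa_seq`), replacing the built-in ORF
#'   caller.
#' @param annotations Optional per-protein annotations for cluster labels.
#' @return An object of class `phagehost_fit`: list with `split`, `genes`,
#'   `clustering`, `cluster_db`, `feature_matrix` (train, filtered), `kept`,
#'   `suite`, `test_matrix`, `report`, `genera`, and `config`.
#' @export
run_pipeline <- function(genomes, labels, config = phagehost_config(),
                         proteins = NULL, annotations = NULL) {
  labels <- dplyr::distinct(labels[, c("phage_id", "genus")])
  labels <- labels[labels$phage_id %in% genomes$id, ]
  genera <- select_top_genera(labels, config$top_n)
  labels <- labels[labels$genus %in% genera, ]
  keep_ids <- genomes$id[genomes$id %in% labels$phage_id]
  genomes <- genomes[genomes$id %in% keep_ids, ]
  split <- split_corpus(genomes$id, fraction = config$fraction,
                        seed = config$seed)
  genes <- if (is.null(proteins)) {
    find_orfs(genomes, min_aa = config$min_aa)
  } else {
    stopifnot(all(c("protein_id", "genome_id", "aa_seq") %in% names(proteins)))
    as_tibble(proteins)
  }
  train_genes <- genes[genes$genome_id %in% split$train_ids, ]
  clustering <- cluster_proteins(train_genes,
                                 n_training_phages = length(split$train_ids),
                                 config = config, annotations = annotations)
  db <- clustering$cluster_db
  m_train <- build_feature_matrix(train_genes, db, phage_ids = split$train_ids)
  vt <- variance_threshold_filter(m_train, max_presence = config$max_presence)
  suite <- train_suite(vt$matrix, labels, genera = genera,
                       min_impurity_split = config$min_impurity_split,
                       balanced = config$balanced)
  test_genes <- genes[genes$genome_id %in% split$test_ids, ]
  test_matrix <- vectorize_corpus(test_genes, db, split$test_ids,
                                  columns = vt$kept,
                                  assign_threshold = config$assign_threshold)
  report <- evaluate_suite(suite, test_matrix, labels,
                           decision_threshold = config$decision_threshold)
  structure(
    list(split = split, genes = genes, clustering = clustering,
         cluster_db = db, feature_matrix = vt$matrix, kept = vt$kept,
         suite = suite, test_matrix = test_matrix, report = report,
         genera = genera, config = config),
    class = "phagehost_fit"
  )
}

#' Vectorize many genomes against a frozen cluster database
#'
#' Applies [vectorize_novel()] to each genome's gene products and stacks the
#' results into a matrix (one row per requested phage; phages without genes
#' get zero rows).
#'
#' @param genes Gene tibble (`protein_id`, `genome_id`, `aa_seq`).
#' @param cluster_db A `cluster_db`.
#' @param phage_ids Row universe and order.
#' @param columns Columns to report (see [vectorize_novel()]).
#' @param assign_threshold Normalized-score assignment threshold.
#' @return Integer matrix `length(phage_ids)` x `length(columns)`.
#' @export
vectorize_corpus <- function(genes, cluster_db, phage_ids, columns = NULL,
                             assign_threshold = 0.4) {
  if (is.null(columns)) columns <- paste0("c", cluster_db$clusters$cluster_id)
  by_phage <- split(genes$aa_seq, factor(genes$genome_id, levels = phage_ids))
  rows <- lapply(phage_ids, function(id) {
    vectorize_novel(by_phage[[id]] %||% character(0), cluster_db,
                    columns = columns, assign_threshold = assign_threshold)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- phage_ids
  m
}

#' Predict hosts for novel genome sequences with a trained model
#'
#' Runs the classification path end to end: call genes on each genome,
#' vectorize against the model's frozen cluster database, and route through
#' every genus tree.
#'
#' @param genomes Genome tibble of novel phages.
#' @param model A list from [read_model()] (or a `phagehost_fit`).
#' @param config Optional [phagehost_config()] overriding `min_aa` and
#'   `assign_threshold`; defaults to the model's embedded configuration.
#' @return A tibble (`phage_id`, `genus`) of predicted admissible hosts.
#' @export
classify_genomes <- function(genomes, model, config = NULL) {
  if (inherits(model, "phagehost_fit")) {
    model <- list(suite = model$suite, cluster_db = model$cluster_db,
                  run_config = model$config)
  }
  cfg <- config %||% model$run_config %||% phagehost_config()
  genes <- find_orfs(genomes, min_aa = cfg$min_aa)
  m <- vectorize_corpus(genes, model$cluster_db, genomes$id,
                        columns = model$suite$columns,
                        assign_threshold = cfg$assign_threshold)
  predict_hosts(m, model$suite,
                decision_threshold = cfg$decision_threshold)
}

#' @export
print.phagehost_fit <- function(x, ...) {
  cat("<phagehost_fit>\n",
      "  corpus: ", length(x$split$train_ids), " train / ",
      length(x$split$test_ids), " test phages, ",
      length(x$genera), " genera\n",
      "  clusters: ", nrow(x$cluster_db$clusters), " kept (",
      length(x$kept), " after variance filter)\n",
      "  aggregate accuracy: ",
      sprintf("%.4f", x$report$aggregate_accuracy), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.phagehost_fit <- function(x, ...) tidy(x$report)

#' @exportS3Method generics::glance
glance.phagehost_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n_train = length(x$split$train_ids),
           n_clusters = nrow(x$cluster_db$clusters),
           n_features = length(x$kept)),
    glance(x$report)
  )
}
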