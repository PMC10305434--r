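#' Greedy deduplication of protein sequences
#'
#' Incremental clustering in descending length order (ties by id): each
#' protein joins the first existing representative whose global-alignment
#' identity (matches / alignment columns, scoring per `config`) reaches
#' `identity_threshold`; otherwise it opens a new representative.
#'
#' @param proteins Tibble with columns `protein_id`, `aa_seq`.
#' @param identity_threshold Identity threshold in (0, 1]; default 0.95.
#' @param config An [align_config()].
#' @return A list with `representatives` (tibble `protein_id`, `aa_seq`) and
#'   `map` (tibble `protein_id`, `representative_id`; representatives map to
#'   themselves).
#' @export
dedup_proteins <- function(proteins, identity_threshold = 0.95,
                           config = align_config()) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            all(c("protein_id", "aa_seq") %in% names(proteins)))
  ord <- order(-nchar(proteins$aa_seq), proteins$protein_id)
  p <- proteins[ord, ]
  assign <- dedup_assign_cpp(p$aa_seq, identity_threshold, score_matrix26(config),
                             config$gap_open, config$gap_extend)
  rep_id <- p$protein_id[assign]
  map <- tibble(protein_id = p$protein_id, representative_id = rep_id)
  reps <- p[p$protein_id %in% unique(rep_id), c("protein_id", "aa_seq")]
  list(representatives = as_tibble(reps), map = map)
}

#' Candidate pairs by shared k-mers
#'
#' A recall-oriented stand-in for a BLAST prefilter: an unordered pair of
#' proteins is a candidate iff the two share at least `min_shared` distinct
#' k-mers. Reflexive pairs are excluded.
#'
#' @param proteins Tibble with columns `protein_id`, `aa_seq`.
#' @param k K-mer length (>= 2); default 4.
#' @param min_shared Minimum number of distinct shared k-mers; default 2.
#' @return Tibble with columns `id_a`, `id_b` (`id_a < id_b`) and
#'   `shared_kmers`.
#' @export
candidate_pairs <- function(proteins, k = 4L, min_shared = 2L) {
  stopifnot(k >= 2, all(c("protein_id", "aa_seq") %in% names(proteins)))
  keep <- nchar(proteins$aa_seq) >= k
  p <- proteins[keep, ]
  if (nrow(p) == 0) {
    return(tibble(id_a = character(0), id_b = character(0),
                  shared_kmers = integer(0)))
  }
  kmer_list <- lapply(p$aa_seq, function(s) {
    unique(substring(s, seq_len(nchar(s) - k + 1L),
                     seq_len(nchar(s) - k + 1L) + k - 1L))
  })
  km <- tibble(
    id = rep(p$protein_id, lengths(kmer_list)),
    kmer = unlist(kmer_list, use.names = FALSE)
  )
  pairs <- dplyr::inner_join(km, km, by = "kmer",
                             relationship = "many-to-many",
                             suffix = c("_a", "_b")) |>
    dplyr::filter(.data$id_a < .data$id_b) |>
    dplyr::count(.data$id_a, .data$id_b, name = "shared_kmers") |>
    dplyr::filter(.data$shared_kmers >= min_shared)
  as_tibble(pairs)
}

#' Build the protein similarity graph
#'
#' Candidate pairs are aligned with [smith_waterman()]; the edge weight is
#' the raw score normalized by the smaller self-alignment score, clipped to
#' [0, 1]. Edges with normalized score below `norm_threshold` are dropped
#' (inclusive `>=` keeps boundary edges). Every node carries a self-loop of
#' weight 1, as the Markov clustering step expects.
#'
#' @param pairs Candidate pairs from [candidate_pairs()].
#' @param proteins Tibble with columns `protein_id`, `aa_seq` (the graph gets
#'   one node per row, including proteins with no candidate pair).
#' @param norm_threshold Minimum normalized score for an edge; default 0.4.
#' @param config An [align_config()].
#' @return An object of class `similarity_graph`: list with `ids`,
#'   `adjacency` (sparse symmetric matrix, unit diagonal), and `edges`
#'   (tibble `protein_a`, `protein_b`, `raw_score`, `norm_score`).
#' @export
build_graph <- function(pairs, proteins, norm_threshold = 0.4,
                        config = align_config()) {
  ids <- proteins$protein_id
  seqs <- stats::setNames(proteins$aa_seq, ids)
  self <- stats::setNames(self_scores(proteins$aa_seq, config), ids)
  edges <- tibble(protein_a = character(0), protein_b = character(0),
                  raw_score = integer(0), norm_score = numeric(0))
  if (nrow(pairs) > 0) {
    raw <- unname(sw_scores(seqs[pairs$id_a], seqs[pairs$id_b], config))
    norm <- unname(norm_scores(raw, self[pairs$id_a], self[pairs$id_b]))
    keep <- norm >= norm_threshold
    edges <- tibble(protein_a = pairs$id_a[keep], protein_b = pairs$id_b[keep],
                    raw_score = raw[keep], norm_score = norm[keep])
  }
  n <- length(ids)
  i <- match(edges$protein_a, ids)
  j <- match(edges$protein_b, ids)
  adj <- Matrix::sparseMatrix(
    i = c(i, j, seq_len(n)), j = c(j, i, seq_len(n)),
    x = c(edges$norm_score, edges$norm_score, rep(1, n)),
    dims = c(n, n), dimnames = list(ids, ids)
  )
  structure(list(ids = ids, adjacency = adj, edges = edges,
                 norm_threshold = norm_threshold),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("<similarity_graph> ", length(x$ids), " nodes, ", nrow(x$edges),
      " edges (norm_threshold ", x$norm_threshold, ")\n", sep = "")
  invisible(x)
}

#' Write a similarity graph as an ABC edge list
#'
#' Three whitespace-separated columns (node, node, weight) — the native input
#' format of the reference MCL implementation, for cross-checking.
#'
#' @param graph A `similarity_graph`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_graph_abc <- function(graph, path) {
  writeLines(paste(graph$edges$protein_a, graph$edges$protein_b,
                   format(graph$edges$norm_score, trim = TRUE)), path)
  invisible(path)
}

#' Markov clustering of a weighted graph
#'
#' The Markov Cluster Algorithm: column-normalize the weighted adjacency
#' matrix (self-loops included), then alternate expansion (matrix power),
#' inflation (elementwise power followed by column renormalization), and
#' pruning of entries below `prune_below`, until the largest elementwise
#' change drops below `tol` or `max_iter` is reached. Clusters are the
#' connected components of the converged matrix's nonzero pattern, so the
#' result is always a partition of the nodes.
#'
#' @param graph A `similarity_graph`, or a square (sparse or dense) weighted
#'   adjacency matrix with dimnames and self-loops on every node.
#' @param inflation Inflation exponent (> 1); default 2.
#' @param expansion Expansion power (integer >= 2); default 2.
#' @param prune_below Entries below this value are zeroed each iteration.
#' @param tol Convergence tolerance on the max elementwise change.
#' @param max_iter Iteration cap; non-convergence raises a warning and the
#'   current matrix is interpreted.
#' @return A list with `membership` (tibble `id`, `cluster`; clusters are
#'   integers 1..K), `iterations`, `converged`, and `flow` (the converged
#'   column-stochastic matrix that was interpreted).
#' @export
mcl <- function(graph, inflation = 2, expansion = 2L, prune_below = 1e-5,
                tol = 1e-6, max_iter = 200L) {
  adj <- if (inherits(graph, "similarity_graph")) graph$adjacency else graph
  adj <- methods::as(methods::as(Matrix::Matrix(adj, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  n <- nrow(adj)
  ids <- rownames(adj)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (any(Matrix::diag(adj) == 0)) {
    abort("mcl expects self-loops on every node")
  }
  col_normalize <- function(m) {
    cs <- Matrix::colSums(m)
    if (any(cs == 0)) abort("zero column encountered during MCL iteration")
    m %*% Matrix::Diagonal(x = 1 / cs)
  }
  m <- col_normalize(adj)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    prev <- m
    # expansion: matrix power
    mexp <- m
    for (p in seq_len(expansion - 1L)) mexp <- mexp %*% m
    # inflation: elementwise power + renormalize
    mexp@x <- mexp@x^inflation
    mexp@x[mexp@x < prune_below] <- 0
    mexp <- Matrix::drop0(mexp)
    m <- col_normalize(mexp)
    delta <- max(abs(m - prev))
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(paste0("MCL did not converge in ", max_iter,
                " iterations; interpreting current matrix"))
  }
  pattern <- m != 0
  pattern <- pattern | Matrix::t(pattern)
  g <- igraph::graph_from_adjacency_matrix(pattern, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  list(membership = tibble(id = ids, cluster = as.integer(comp$membership)),
       iterations = iter, converged = converged, flow = m)
}

#' Propagate cluster assignments from representatives to duplicates
#'
#' Inverts the deduplication step: every protein inherits the cluster of its
#' representative.
#'
#' @param membership Tibble (`id`, `cluster`) over representatives, e.g. from
#'   [mcl()].
#' @param dedup_map Tibble (`protein_id`, `representative_id`) from
#'   [dedup_proteins()].
#' @return Tibble (`protein_id`, `cluster`) over all proteins.
#' @export
expand_clusters <- function(membership, dedup_map) {
  idx <- match(dedup_map$representative_id, membership$id)
  if (anyNA(idx)) {
    orphan <- dedup_map$representative_id[which(is.na(idx))[1]]
    abort(paste0("duplicate maps to unclustered representative ", orphan))
  }
  tibble(protein_id = dedup_map$protein_id,
         cluster = membership$cluster[idx])
}

#' Prevalence filter and cluster database construction
#'
#' Computes each cluster's prevalence — the fraction of training phages
#' contributing at least one member — and removes clusters whose prevalence
#' is strictly below `min_prevalence` (a cluster at exactly the threshold is
#' kept). Survivors are re-indexed with dense ids `0..K-1` in order of
#' descending prevalence, ties by smallest member id. The representative of
#' a cluster is its longest member (ties by lexicographically smallest id).
#'
#' @param membership Tibble (`protein_id`, `cluster`) over all clustered
#'   proteins, e.g. from [expand_clusters()].
#' @param genes Gene tibble mapping proteins to phages (columns `protein_id`,
#'   `genome_id`, `aa_seq`; [find_orfs()] output works).
#' @param n_training_phages Number of phages in the training corpus (the
#'   prevalence denominator).
#' @param min_prevalence Removal threshold; default 0.01 (clusters in fewer
#'   than 1 percent of training phages are dropped).
#' @param annotations Optional tibble (`protein_id`, `annotation`); a cluster
#'   is annotated with its members' most frequent annotation.
#' @param config Alignment configuration snapshot stored in the database.
#' @return An object of class `cluster_db`: list with `clusters` (tibble
#'   `cluster_id`, `representative_id`, `representative_seq`, `n_members`,
#'   `n_phages`, `prevalence`, `annotation`), `membership` (tibble
#'   `protein_id`, `cluster_id`), and `config`.
#' @export
filter_clusters <- function(membership, genes, n_training_phages,
                            min_prevalence = 0.01, annotations = NULL,
                            config = align_config()) {
  stopifnot(n_training_phages >= 1)
  info <- membership |>
    dplyr::inner_join(genes[, c("protein_id", "genome_id", "aa_seq")],
                      by = "protein_id")
  if (nrow(info) < nrow(membership)) {
    abort("membership references proteins absent from the gene table")
  }
  stats <- info |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      n_phages = dplyr::n_distinct(.data$genome_id),
      min_member = min(.data$protein_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(prevalence = .data$n_phages / .env$n_training_phages)
  # strict "< threshold" removal, robust to floating-point representation
  keep <- stats$n_phages >= min_prevalence * n_training_phages - 1e-9
  if (!any(keep)) {
    abort(paste0("all clusters fall below the prevalence threshold ",
                 min_prevalence, "; lower min_prevalence"))
  }
  kept <- stats[keep, ]
  kept <- kept[order(-kept$prevalence, kept$min_member), ]
  kept$cluster_id <- seq_len(nrow(kept)) - 1L
  reps <- info |>
    dplyr::filter(.data$cluster %in% kept$cluster) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::arrange(dplyr::desc(nchar(.data$aa_seq)), .data$protein_id,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("cluster", representative_id = "protein_id",
                  representative_seq = "aa_seq")
  clusters <- kept |>
    dplyr::left_join(reps, by = "cluster") |>
    dplyr::select("cluster_id", "representative_id", "representative_seq",
                  "n_members", "n_phages", "prevalence",
                  old_cluster = "cluster")
  clusters$annotation <- NA_character_
  if (!is.null(annotations)) {
    ann <- info |>
      dplyr::inner_join(annotations, by = "protein_id") |>
      dplyr::count(.data$cluster, .data$annotation) |>
      dplyr::group_by(.data$cluster) |>
      dplyr::arrange(dplyr::desc(.data$n), .data$annotation, .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
    idx <- match(clusters$old_cluster, ann$cluster)
    clusters$annotation <- ann$annotation[idx]
  }
  new_membership <- membership |>
    dplyr::inner_join(clusters[, c("old_cluster", "cluster_id")],
                      by = c(cluster = "old_cluster")) |>
    dplyr::select("protein_id", "cluster_id")
  clusters$old_cluster <- NULL
  structure(list(clusters = as_tibble(clusters),
                 membership = as_tibble(new_membership),
                 config = config),
            class = "cluster_db")
}

#' @export
print.cluster_db <- function(x, ...) {
  cat("<cluster_db> ", nrow(x$clusters), " clusters over ",
      nrow(x$membership), " proteins\n", sep = "")
  invisible(x)
}

#' Write a cluster summary TSV
#'
#' @param db A `cluster_db`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cluster_summary <- function(db, path) {
  tbl <- db$clusters[, c("cluster_id", "n_members", "n_phages", "prevalence",
                         "representative_id", "annotation")]
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Cluster a training corpus's gene products end to end
#'
#' Convenience orchestrator: deduplicate, find candidate pairs, build the
#' similarity graph, run Markov clustering, propagate clusters back to all
#' proteins, and apply the prevalence filter.
#'
#' @param genes Gene-call tibble ([find_orfs()] output) restricted to
#'   training phages.
#' @param n_training_phages Prevalence denominator (defaults to the number of
#'   distinct genomes in `genes`).
#' @param config A [phagehost_config()].
#' @param annotations Optional per-protein annotations (see
#'   [filter_clusters()]).
#' @return A list with `cluster_db`, `graph`, `partition` (full pre-filter
#'   membership), `dedup`, and `mcl` (iteration diagnostics).
#' @export
cluster_proteins <- function(genes, n_training_phages = dplyr::n_distinct(genes$genome_id),
                             config = phagehost_config(), annotations = NULL) {
  acfg <- align_config(gap_open = config$gap_open, gap_extend = config$gap_extend)
  dd <- dedup_proteins(genes[, c("protein_id", "aa_seq")],
                       identity_threshold = config$identity_threshold,
                       config = acfg)
  pairs <- candidate_pairs(dd$representatives, k = config$k,
                           min_shared = config$min_shared)
  graph <- build_graph(pairs, dd$representatives,
                       norm_threshold = config$norm_threshold, config = acfg)
  part <- mcl(graph, inflation = config$inflation, expansion = config$expansion,
              prune_below = config$prune_below, tol = config$mcl_tol,
              max_iter = config$mcl_max_iter)
  full <- expand_clusters(part$membership, dd$map)
  db <- filter_clusters(full, genes, n_training_phages,
                        min_prevalence = config$min_prevalence,
                        annotations = annotations, config = acfg)
  list(cluster_db = db, graph = graph, partition = full, dedup = dd,
       mcl = part[c("iterations", "converged")])
}
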