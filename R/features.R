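#' Build the phage-by-cluster feature matrix
#'
#' Entry `a[i, j]` counts the genes of phage `i` assigned to cluster `j`.
#' Phages with no clustered gene keep an all-zero row. Column order follows
#' the cluster database (dense ids `0..K-1`), with column names `c<id>`.
#'
#' @param genes Gene tibble (`protein_id`, `genome_id`).
#' @param cluster_db A `cluster_db` from [filter_clusters()]; its membership
#'   maps proteins to kept clusters.
#' @param phage_ids Row universe and order. Defaults to the distinct genomes
#'   in `genes`.
#' @return Integer matrix with `phage_ids` rownames and `c<id>` colnames.
#' @export
build_feature_matrix <- function(genes, cluster_db,
                                 phage_ids = unique(genes$genome_id)) {
  stopifnot(inherits(cluster_db, "cluster_db"))
  if (nrow(cluster_db$clusters) == 0) abort("empty cluster database")
  cl_ids <- cluster_db$clusters$cluster_id
  cols <- paste0("c", cl_ids)
  m <- matrix(0L, nrow = length(phage_ids), ncol = length(cl_ids),
              dimnames = list(phage_ids, cols))
  assigned <- dplyr::inner_join(cluster_db$membership,
                                genes[, c("protein_id", "genome_id")],
                                by = "protein_id")
  if (nrow(assigned) < nrow(cluster_db$membership)) {
    abort("cluster membership references proteins absent from the gene table")
  }
  if (!all(assigned$cluster_id %in% cl_ids)) {
    abort("protein mapped to a cluster absent from the database")
  }
  assigned <- assigned[assigned$genome_id %in% phage_ids, ]
  if (nrow(assigned) > 0) {
    counts <- assigned |>
      dplyr::count(.data$genome_id, .data$cluster_id)
    m[cbind(match(counts$genome_id, phage_ids),
            match(counts$cluster_id, cl_ids))] <- as.integer(counts$n)
  }
  m
}

#' Variance-threshold column filter
#'
#' Each column is binarized to presence (`count >= 1`) for the test only: a
#' column is dropped iff its presence fraction exceeds `max_presence` or its
#' absence fraction does (strictly "more than", so a column present in
#' exactly 99 percent of phages survives the default). Surviving columns keep
#' their integer counts and original cluster ids.
#'
#' @param m Feature matrix from [build_feature_matrix()].
#' @param max_presence Fraction threshold; default 0.99.
#' @return A list with `matrix` (reduced) and `kept` (surviving column
#'   names).
#' @export
variance_threshold_filter <- function(m, max_presence = 0.99) {
  stopifnot(is.matrix(m), nrow(m) > 0, ncol(m) > 0)
  n <- nrow(m)
  present <- colSums(m >= 1L)
  # strict "> threshold" drops, robust to floating-point representation
  drop <- present > max_presence * n + 1e-9 |
    (n - present) > max_presence * n + 1e-9
  if (all(drop)) abort("variance threshold filter dropped every column")
  kept <- colnames(m)[!drop]
  list(matrix = m[, !drop, drop = FALSE], kept = kept)
}

#' Vectorize a novel genome against a frozen cluster database
#'
#' Each gene product is aligned (same scoring configuration as training)
#' against the representatives of the kept clusters; clusters whose
#' normalized score reaches `assign_threshold` are candidates, and the gene
#' counts once toward the best-scoring candidate (ties to the smallest
#' cluster id). Genes with no candidate stay unassigned. The result is an
#' integer count vector over the requested columns.
#'
#' @param aa_seqs Character vector of one genome's protein sequences (may be
#'   empty, giving a zero vector).
#' @param cluster_db A `cluster_db` from training.
#' @param columns Column names (`c<id>`) to report, typically the
#'   variance-filter survivors. Defaults to all clusters in the database.
#' @param assign_threshold Normalized-score threshold; default 0.4 (the
#'   training edge threshold).
#' @return Named integer vector over `columns`.
#' @export
vectorize_novel <- function(aa_seqs, cluster_db, columns = NULL,
                            assign_threshold = 0.4) {
  stopifnot(inherits(cluster_db, "cluster_db"))
  cl <- cluster_db$clusters
  if (is.null(columns)) columns <- paste0("c", cl$cluster_id)
  out <- stats::setNames(integer(length(columns)), columns)
  if (length(aa_seqs) == 0 || nrow(cl) == 0) return(out)
  config <- cluster_db$config
  rep_self <- self_scores(cl$representative_seq, config)
  q_self <- self_scores(aa_seqs, config)
  for (g in seq_along(aa_seqs)) {
    raw <- sw_scores(rep(aa_seqs[g], nrow(cl)), cl$representative_seq, config)
    norm <- norm_scores(raw, q_self[g], rep_self)
    cand <- which(norm >= assign_threshold)
    if (length(cand) == 0) next
    best <- cand[order(-norm[cand], cl$cluster_id[cand])][1]
    col <- paste0("c", cl$cluster_id[best])
    if (col %in% columns) out[col] <- out[col] + 1L
  }
  out
}
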