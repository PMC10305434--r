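toy_db <- function(clusters, membership, genes) {
  reps <- membership |>
    dplyr::inner_join(genes, by = "protein_id") |>
    dplyr::group_by(cluster_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  structure(list(
    clusters = tibble::tibble(
      cluster_id = clusters,
      representative_id = reps$protein_id[match(clusters, reps$cluster_id)],
      representative_seq = reps$aa_seq[match(clusters, reps$cluster_id)],
      n_members = as.integer(table(factor(membership$cluster_id, clusters))),
      n_phages = NA_integer_, prevalence = NA_real_,
      annotation = NA_character_),
    membership = membership,
    config = align_config()),
    class = "cluster_db")
}

test_that("feature matrix counts genes per cluster with zero rows preserved", {
  genes <- tibble::tibble(
    protein_id = c("p1_1", "p1_2", "p1_3", "p2_1"),
    genome_id = c("p1", "p1", "p1", "p2"),
    aa_seq = strrep("M", 31)
  )
  membership <- tibble::tibble(protein_id = c("p1_1", "p1_2", "p1_3"),
                               cluster_id = c(7L, 7L, 2L))
  db <- toy_db(c(2L, 7L), membership, genes)
  m <- build_feature_matrix(genes, db, phage_ids = c("p1", "p2", "p3"))
  expect_equal(m["p1", "c7"], 2L)
  expect_equal(m["p1", "c2"], 1L)
  expect_equal(unname(m["p2", ]), c(0L, 0L))   # genes but none clustered
  expect_equal(unname(m["p3", ]), c(0L, 0L))   # no genes at all
  expect_equal(colnames(m), c("c2", "c7"))

  empty <- toy_db(integer(0),
                  tibble::tibble(protein_id = character(0), cluster_id = integer(0)),
                  genes)
  expect_error(build_feature_matrix(genes, empty), "empty cluster database")
})

test_that("variance threshold drops only columns beyond the strict 99% rule", {
  m1 <- matrix(0L, nrow = 1000, ncol = 2,
               dimnames = list(paste0("p", 1:1000), c("c0", "c1")))
  m1[1:995, 1] <- 1L   # presence 0.995 > 0.99 -> dropped
  m1[1:500, 2] <- 2L   # presence 0.5 -> kept
  out <- variance_threshold_filter(m1)
  expect_equal(out$kept, "c1")

  m2 <- matrix(0L, nrow = 100, ncol = 2,
               dimnames = list(paste0("p", 1:100), c("c0", "c1")))
  m2[1:99, 1] <- 1L    # presence exactly 0.99, not greater -> kept
  m2[1:50, 2] <- 1L
  expect_setequal(variance_threshold_filter(m2)$kept, c("c0", "c1"))

  m3 <- matrix(1L, nrow = 10, ncol = 1, dimnames = list(paste0("p", 1:10), "c0"))
  expect_error(variance_threshold_filter(m3), "every column")
})

test_that("variance threshold at 1.0 keeps mixed-presence columns unchanged", {
  fit <- small_fit()
  m <- fit$feature_matrix
  out <- variance_threshold_filter(m, max_presence = 1)
  expect_identical(out$matrix, m)
})

test_that("novel vectorization assigns each gene to its best cluster only", {
  withr::with_seed(91, {
    base <- random_peptide(60)
    near <- strsplit(base, "")[[1]]
    for (p in sample(60, 6)) near[p] <- setdiff(rownames(oracle_blosum62()), near[p])[1]
    near <- paste(near, collapse = "")
    far <- strsplit(base, "")[[1]]
    for (p in sample(60, 20)) far[p] <- setdiff(rownames(oracle_blosum62()), far[p])[1]
    far <- paste(far, collapse = "")
    genes <- tibble::tibble(protein_id = c("r1_1", "r2_1"),
                            genome_id = c("r1", "r2"),
                            aa_seq = c(near, far))
    membership <- tibble::tibble(protein_id = c("r1_1", "r2_1"),
                                 cluster_id = c(3L, 9L))
    db <- toy_db(c(3L, 9L), membership, genes)
    n_near <- norm_scores(smith_waterman(base, near)$score,
                          self_scores(base), self_scores(near))
    n_far <- norm_scores(smith_waterman(base, far)$score,
                         self_scores(base), self_scores(far))
    expect_gt(n_near, n_far)
    expect_gt(n_far, 0.4) # both clusters are candidates
    v <- vectorize_novel(base, db)
    expect_equal(unname(v[c("c3", "c9")]), c(1L, 0L)) # best cluster only
    # identical to a representative -> counts there
    v2 <- vectorize_novel(near, db)
    expect_equal(unname(v2["c3"]), 1L)
    # dissimilar protein stays unassigned
    v3 <- vectorize_novel(random_peptide(60), db)
    expect_equal(sum(v3), 0L)
    # no proteins -> zero vector
    expect_equal(sum(vectorize_novel(character(0), db)), 0L)
  })
})

test_that("re-vectorizing a training phage reproduces its matrix row without noise", {
  corp <- cached_fixture("corpus_mut0_small",
                         generate_corpus(small_spec(mutation_rate = 0)))
  fit <- cached_fixture("fit_mut0_small", suppressWarnings(
    run_pipeline(corp$genomes, corp$labels, config = phagehost_config(seed = 5))))
  id <- fit$split$train_ids[1]
  aa <- fit$genes$aa_seq[fit$genes$genome_id == id]
  v <- vectorize_novel(aa, fit$cluster_db, columns = fit$kept)
  expect_equal(v, fit$feature_matrix[id, ])
})

test_that("vector entries never exceed the phage's gene count", {
  fit <- small_fit()
  genes_per_phage <- table(fit$genes$genome_id)
  for (id in fit$split$test_ids) {
    expect_lte(sum(fit$test_matrix[id, ]), genes_per_phage[[id]])
  }
})
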