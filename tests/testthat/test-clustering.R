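prot_tbl <- function(...) {
  seqs <- c(...)
  tibble::tibble(protein_id = names(seqs), aa_seq = unname(seqs))
}

test_that("deduplication merges identical sequences and honors the threshold", {
  p <- prot_tbl(a = "MKPGMKPG", b = "MKPGMKPG")
  dd <- dedup_proteins(p)
  expect_equal(nrow(dd$representatives), 1)
  expect_setequal(dd$map$protein_id, c("a", "b"))
  expect_equal(unique(dd$map$representative_id), "a")

  # one residue apart at threshold 1.0 -> kept separate
  p2 <- prot_tbl(a = "MKPGMKPG", b = "MKPGMKPA")
  dd2 <- dedup_proteins(p2, identity_threshold = 1)
  expect_equal(nrow(dd2$representatives), 2)
})

test_that("a 93%-identical pair stays separate at the 0.95 threshold", {
  withr::with_seed(61, {
    av <- strsplit(random_peptide(100), "")[[1]]
    bv <- av
    for (p in sample(100, 7)) bv[p] <- setdiff(rownames(oracle_blosum62()), av[p])[1]
    p <- prot_tbl(a = paste(av, collapse = ""), b = paste(bv, collapse = ""))
    expect_equal(align_identity(p$aa_seq[1], p$aa_seq[2])$identity, 0.93)
    expect_equal(nrow(dedup_proteins(p, 0.95)$representatives), 2)
    expect_equal(nrow(dedup_proteins(p, 0.90)$representatives), 1)
  })
})

test_that("candidate pairs require the stated number of shared k-mers", {
  s <- random_peptide(50)
  expect_equal(nrow(candidate_pairs(prot_tbl(a = s, b = s))), 1)
  p <- prot_tbl(a = strrep("A", 30), b = strrep("W", 30))
  expect_equal(nrow(candidate_pairs(p)), 0)
  # exactly two distinct shared 4-mers (boundary at min_shared = 2)
  p2 <- prot_tbl(a = "MKPGWDDDDDHECT", b = "MKPGYVVVVVHECT")
  shared <- length(intersect(
    unique(substring(p2$aa_seq[1], 1:11, 4:14)),
    unique(substring(p2$aa_seq[2], 1:11, 4:14))))
  expect_equal(shared, 2) # "MKPG" and "HECT"
  got <- candidate_pairs(p2, k = 4, min_shared = 2)
  expect_equal(nrow(got), 1)
  expect_equal(candidate_pairs(p2, k = 4, min_shared = 3) |> nrow(), 0)
})

test_that("similarity graph applies the inclusive edge threshold and self-loops", {
  withr::with_seed(71, {
    a <- random_peptide(40)
    bv <- strsplit(a, "")[[1]]
    for (p in sample(40, 12)) bv[p] <- setdiff(rownames(oracle_blosum62()), bv[p])[1]
    b <- paste(bv, collapse = "")
    p <- prot_tbl(a = a, b = b, lone = random_peptide(35))
    pairs <- tibble::tibble(id_a = "a", id_b = "b", shared_kmers = 5L)
    raw <- smith_waterman(a, b)$score
    nrm <- norm_scores(raw, self_scores(a), self_scores(b))
    g_in <- build_graph(pairs, p, norm_threshold = nrm)        # inclusive >=
    g_out <- build_graph(pairs, p, norm_threshold = nrm + 1e-9) # just above
    expect_equal(nrow(g_in$edges), 1)
    expect_equal(g_in$edges$norm_score, nrm)
    expect_equal(nrow(g_out$edges), 0)
    expect_equal(unname(Matrix::diag(g_in$adjacency)), rep(1, 3))
    expect_true(Matrix::isSymmetric(g_in$adjacency))
  })
})

test_that("identical sequences get edge weight 1", {
  s <- random_peptide(30)
  g <- build_graph(tibble::tibble(id_a = "a", id_b = "b"),
                   prot_tbl(a = s, b = s))
  expect_equal(g$edges$norm_score, 1)
})

test_that("Markov clustering separates disconnected cliques and singletons", {
  ids <- letters[1:6]
  tri2 <- Matrix::sparseMatrix(i = c(1, 1, 2, 4, 4, 5), j = c(2, 3, 3, 5, 6, 6),
                               x = 1, dims = c(6, 6),
                               dimnames = list(ids, ids), symmetric = TRUE)
  tri2 <- methods::as(tri2, "generalMatrix") + Matrix::Diagonal(6)
  res <- mcl(tri2)
  expect_true(res$converged)
  expect_equal(res$membership$cluster[1:3], rep(res$membership$cluster[1], 3))
  expect_equal(res$membership$cluster[4:6], rep(res$membership$cluster[4], 3))
  expect_equal(length(unique(res$membership$cluster)), 2)

  single <- Matrix::Matrix(1, 1, 1, dimnames = list("x", "x"))
  expect_equal(nrow(mcl(single)$membership), 1)
})

test_that("Markov clustering splits two cliques at a weak bridge like the reference", {
  ids <- paste0("n", 1:8)
  m <- matrix(0, 8, 8, dimnames = list(ids, ids))
  m[1:4, 1:4] <- 1
  m[5:8, 5:8] <- 1
  m[4, 5] <- m[5, 4] <- 0.1
  res <- mcl(Matrix::Matrix(m, sparse = TRUE), inflation = 2)
  cl <- res$membership$cluster
  expect_equal(length(unique(cl)), 2)
  expect_equal(cl[1:4], rep(cl[1], 4))
  expect_equal(cl[5:8], rep(cl[5], 4))
  # independent dense reference implementation agrees
  expect_true(same_partition(cl, mcl_oracle(m)))
})

test_that("Markov clustering yields partitions that never cross components", {
  withr::with_seed(81, {
    for (rep in 1:50) {
      n <- sample(4:12, 1)
      m <- matrix(0, n, n)
      edges <- which(upper.tri(m) & matrix(runif(n * n) < 0.3, n, n))
      m[edges] <- runif(length(edges), 0.2, 1)
      m <- m + t(m)
      diag(m) <- 1
      dimnames(m) <- list(paste0("v", 1:n), paste0("v", 1:n))
      res <- mcl(Matrix::Matrix(m, sparse = TRUE))
      # a partition: every node in exactly one cluster
      expect_equal(nrow(res$membership), n)
      expect_false(anyNA(res$membership$cluster))
      # converged flow is column-stochastic before interpretation
      expect_true(all(abs(Matrix::colSums(res$flow) - 1) < 1e-9))
      # clusters never span distinct connected components of the input
      comp <- mcl_oracle(m, max_iter = 0) # 0 iterations: raw components
      for (cl in unique(res$membership$cluster)) {
        nodes <- which(res$membership$cluster == cl)
        expect_equal(length(unique(comp[nodes])), 1)
      }
    }
  })
})

test_that("cluster expansion propagates representatives and flags orphans", {
  membership <- tibble::tibble(id = c("r1", "r2"), cluster = c(3L, 5L))
  map <- tibble::tibble(protein_id = c("r1", "d1", "d2", "r2"),
                        representative_id = c("r1", "r1", "r1", "r2"))
  out <- expand_clusters(membership, map)
  expect_equal(out$cluster[out$protein_id %in% c("d1", "d2")], c(3L, 3L))
  bad <- tibble::tibble(protein_id = "d9", representative_id = "zz")
  expect_error(expand_clusters(membership, bad), "unclustered representative zz")
})

test_that("prevalence filter removes below 1% strictly and re-indexes densely", {
  # 200 training phages; cluster A in 1 phage (0.005), B in 2 (0.01), C in all
  genes <- tibble::tibble(
    protein_id = c("p001_1", "p002_1", "p003_1",
                   paste0(sprintf("p%03d", 1:200), "_9")),
    genome_id = c("p001", "p002", "p003", sprintf("p%03d", 1:200)),
    aa_seq = strrep("M", 31)
  )
  membership <- tibble::tibble(
    protein_id = genes$protein_id,
    cluster = c(1L, 2L, 2L, rep(3L, 200))
  )
  db <- filter_clusters(membership, genes, n_training_phages = 200)
  expect_setequal(db$clusters$prevalence, c(0.01, 1))
  expect_equal(db$clusters$cluster_id, c(0L, 1L))
  expect_equal(db$clusters$prevalence[db$clusters$cluster_id == 0L], 1)
  expect_false("p001_1" %in% db$membership$protein_id) # 0.005 removed
  expect_true("p002_1" %in% db$membership$protein_id)  # exactly 0.01 kept
  expect_error(filter_clusters(membership, genes, n_training_phages = 200,
                               min_prevalence = 2),
               "prevalence threshold")
})

test_that("raising the prevalence threshold only ever removes clusters", {
  fit <- small_fit()
  part <- fit$clustering$partition
  genes <- fit$genes[fit$genes$protein_id %in% part$protein_id, ]
  n <- length(fit$split$train_ids)
  kept_for <- function(thr) {
    db <- filter_clusters(part, genes, n, min_prevalence = thr)
    sort(db$clusters$representative_id)
  }
  thresholds <- c(0.001, 0.01, 0.05, 0.2, 0.5)
  keeps <- lapply(thresholds, kept_for)
  for (i in seq_len(length(keeps) - 1)) {
    expect_true(all(keeps[[i + 1]] %in% keeps[[i]]))
  }
})

test_that("cluster representatives are the longest members with id tie-break", {
  genes <- tibble::tibble(
    protein_id = c("g1_1", "g1_2", "g2_1"),
    genome_id = c("g1", "g1", "g2"),
    aa_seq = c("MKPGW", "MKP", "MKPGV")
  )
  membership <- tibble::tibble(protein_id = genes$protein_id,
                               cluster = c(1L, 1L, 1L))
  db <- filter_clusters(membership, genes, n_training_phages = 2)
  expect_equal(db$clusters$representative_id, "g1_1") # length 5, smallest id
  expect_equal(db$clusters$n_members, 3L)
})

test_that("ABC graph export matches the edge list", {
  fit <- small_fit()
  f <- withr::local_tempfile(fileext = ".abc")
  write_graph_abc(fit$clustering$graph, f)
  lines <- readLines(f)
  expect_equal(length(lines), nrow(fit$clustering$graph$edges))
  expect_true(all(lengths(strsplit(lines, " ")) == 3))
})
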