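# Independent oracles: every routine here is written against the textbook
# definition only, deliberately sharing no code with the package paths it
# checks.

# BLOSUM62 over the 20 standard residues straight from Biostrings' data set
oracle_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V")
      cache <<- e$BLOSUM62[aa, aa]
    }
    cache
  }
})

# quadratic brute-force Smith-Waterman with affine gaps (gap of length L
# costs go + L * ge); plain R matrices, no pruning
sw_oracle <- function(a, b, go = 11, ge = 1) {
  sub <- oracle_blosum62()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  if (n == 0 || m == 0) return(0)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - go - ge, E[i, j - 1] - ge)
      F[i, j] <- max(H[i - 1, j] - go - ge, F[i - 1, j] - ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
    }
  }
  max(H)
}

random_peptide <- function(len) {
  paste(sample(rownames(oracle_blosum62()), len, replace = TRUE),
        collapse = "")
}

# dense reference MCL: same scheme, base-R matrices, hand-rolled BFS for the
# final components (no igraph, no Matrix)
mcl_oracle <- function(adj, inflation = 2, expansion = 2, prune = 1e-5,
                       tol = 1e-6, max_iter = 200) {
  m <- as.matrix(adj)
  normalize <- function(x) sweep(x, 2, colSums(x), "/")
  m <- normalize(m)
  for (it in seq_len(max_iter)) {
    prev <- m
    mp <- m
    for (p in seq_len(expansion - 1)) mp <- mp %*% m
    mp <- mp^inflation
    mp[mp < prune] <- 0
    m <- normalize(mp)
    if (max(abs(m - prev)) < tol) break
  }
  pat <- (m != 0) | t(m != 0)
  n <- nrow(pat)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(pat[v, ] & is.na(comp)))
    }
  }
  comp
}

# two partitions agree iff they induce the same equivalence classes
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}
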