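GENUS_POOL <- c("Escherichia", "Salmonella", "Klebsiella", "Pseudomonas",
                "Staphylococcus", "Enterococcus", "Bacillus", "Vibrio",
                "Streptococcus", "Acinetobacter", "Cronobacter", "Citrobacter",
                "Listeria", "Proteus", "Yersinia", "Shigella", "Enterobacter",
                "Campylobacter", "Lactococcus", "Clostridium")

# 22-nt insulator flanking every planted gene: stop codons in all three
# frames on both strands and no start codon on either strand (the block is
# G-free forward; its reverse complement carries TAA/TAG in every frame).
# Guarantees that no ORF of the scanner's minimum length can extend across a
# gene boundary, so the only long ORFs in a clean genome are the planted
# genes themselves.
INSULATOR <- "TAACTAACTAATTACTTACTTA"

#' Specification of a synthetic phage corpus
#'
#' Defines the study conditions for the planted-family benchmark: phages of
#' one host genus share `markers_per_genus` homologous marker gene families;
#' all phages additionally draw background genes from a pool shared across
#' genera (non-informative clusters the filters and trees must ignore);
#' per-nucleotide substitution noise emulates sequence divergence within a
#' family.
#'
#' @param n_genera Number of host genera; default 5.
#' @param phages_per_genus Phages per genus; default 40.
#' @param markers_per_genus Genus-specific marker families; default 3.
#' @param marker_len_aa Length range (residues) of marker proteins; default
#'   c(50, 150).
#' @param background_pool_size Shared background families; default 20 (may
#'   be 0).
#' @param background_genes_per_phage Background genes per phage, drawn
#'   without replacement; default 5.
#' @param mutation_rate Per-nucleotide substitution probability in [0, 0.5);
#'   default 0.02. Substitutions never create an internal stop and never
#'   touch the start or stop codon, so ORF integrity is preserved.
#' @param spacer_len Length range of the random intergenic segment between
#'   the insulators; default c(20, 60).
#' @param seed Integer seed fixing the full corpus; default 42.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genera = 5L, phages_per_genus = 40L,
                           markers_per_genus = 3L,
                           marker_len_aa = c(50L, 150L),
                           background_pool_size = 20L,
                           background_genes_per_phage = 5L,
                           mutation_rate = 0.02,
                           spacer_len = c(20L, 60L),
                           seed = 42L) {
  spec <- list(n_genera = as.integer(n_genera),
               phages_per_genus = as.integer(phages_per_genus),
               markers_per_genus = as.integer(markers_per_genus),
               marker_len_aa = as.integer(marker_len_aa),
               background_pool_size = as.integer(background_pool_size),
               background_genes_per_phage = as.integer(background_genes_per_phage),
               mutation_rate = mutation_rate,
               spacer_len = as.integer(spacer_len),
               seed = as.integer(seed))
  if (spec$n_genera < 1 || spec$phages_per_genus < 1 ||
      spec$markers_per_genus < 1) {
    abort("n_genera, phages_per_genus and markers_per_genus must be >= 1")
  }
  if (spec$background_pool_size < 0 || spec$background_genes_per_phage < 0 ||
      spec$background_genes_per_phage > max(spec$background_pool_size, 0L)) {
    abort("background_genes_per_phage must be between 0 and background_pool_size")
  }
  if (spec$mutation_rate < 0 || spec$mutation_rate >= 0.5) {
    abort("mutation_rate must be in [0, 0.5)")
  }
  if (spec$n_genera > length(GENUS_POOL)) {
    abort(paste0("at most ", length(GENUS_POOL), " genera supported"))
  }
  structure(spec, class = "synthetic_spec")
}

# sample() treats a length-1 numeric as 1:n; these avoid that trap
resample1 <- function(x) x[sample.int(length(x), 1L)]
reshuffle <- function(x) x[sample.int(length(x))]

# synonymous codon sets keyed by residue
synonymous_codons <- function() {
  if (is.null(the_cache$syn_codons)) {
    cm <- codon_map()
    cm <- cm[!cm %in% "*"]
    the_cache$syn_codons <- split(names(cm), cm)
  }
  the_cache$syn_codons
}

random_protein <- function(len) {
  paste0("M", paste(sample(AA_STANDARD, len - 1L, replace = TRUE),
                    collapse = ""))
}

# Fixed 4-codon scaffold (residues LTNY) whose 12-nt window carries a stop
# codon in both shifted forward frames and in all three reverse-strand
# frames, while encoding ordinary residues in frame. Spliced into every
# family protein at regular intervals it caps off-frame and reverse-strand
# stop-free runs at ~21 codons, so no shadow ORF can reach the scanner's
# 30-residue minimum (a run of R codons can extend by at most 3 codons into
# the flanking insulator).
SCAFFOLD_RES <- c("L", "T", "N", "Y")
SCAFFOLD_COD <- c("CTA", "ACT", "AAC", "TAC")

# Draw a family protein of the requested length together with its coding
# sequence: random residues with random synonymous codons, interrupted by
# the stop-scaffold every 17 residues.
draw_family_gene <- function(len) {
  syn <- synonymous_codons()
  residues <- "M"
  codons <- "ATG"
  while (length(residues) < len) {
    n_rand <- min(17L, len - length(residues))
    rr <- sample(AA_STANDARD, n_rand, replace = TRUE)
    cc <- vapply(rr, function(r) {
      opts <- syn[[r]]
      if (length(opts) == 1) opts else sample(opts, 1L)
    }, character(1), USE.NAMES = FALSE)
    residues <- c(residues, rr)
    codons <- c(codons, cc)
    if (length(residues) < len) {
      n_sc <- min(4L, len - length(residues))
      residues <- c(residues, SCAFFOLD_RES[seq_len(n_sc)])
      codons <- c(codons, SCAFFOLD_COD[seq_len(n_sc)])
    }
  }
  nt <- paste0(paste(codons, collapse = ""), "TAA")
  list(aa = paste(residues, collapse = ""), nt = nt)
}

# per-frame longest stop-free runs (shifted forward + reverse frames)
frame_maxes <- function(nt) frame_maxes_cpp(nt)

# nucleotide coordinates are codon-internal only; substitutions creating an
# in-frame stop are skipped
mutate_gene <- function(nt, rate) {
  if (rate <= 0) return(nt)
  n <- nchar(nt)
  positions <- which(runif(n) < rate)
  positions <- positions[positions > 3L & positions <= n - 3L]
  if (length(positions) == 0) return(nt)
  bases <- c("A", "C", "G", "T")
  for (p in positions) {
    old <- substr(nt, p, p)
    new <- sample(setdiff(bases, old), 1L)
    cod_start <- ((p - 1L) %/% 3L) * 3L + 1L
    candidate <- nt
    substr(candidate, p, p) <- new
    if (substr(candidate, cod_start, cod_start + 2L) %in% STOP_CODONS) next
    nt <- candidate
  }
  nt
}

random_spacer <- function(len_range) {
  len <- resample1(seq(len_range[1], len_range[2]))
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate a synthetic phage corpus with planted gene families
#'
#' Draws genus-specific marker protein families and a shared background
#' pool, encodes each gene as `ATG` + codons + `TAA`, applies seeded
#' per-nucleotide substitution noise, and assembles each genome as planted
#' genes in random order separated by insulated random spacers. Every gene's
#' true family and coordinates are recorded, so clustering and tree training
#' can be scored against ground truth.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `genomes` (tibble `id`, `sequence`, `description`),
#'   `labels` (tibble `phage_id`, `genus`), `truth` (tibble `genome_id`,
#'   `start`, `end`, `strand`, `family`, `role`, `genus`), and `families`
#'   (tibble `family`, `role`, `genus`, `aa_seq`).
#' @export
generate_corpus <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    genera <- GENUS_POOL[seq_len(spec$n_genera)]
    fam_rows <- list()
    for (g in genera) {
      for (k in seq_len(spec$markers_per_genus)) {
        len <- resample1(seq(spec$marker_len_aa[1], spec$marker_len_aa[2]))
        fam <- draw_family_gene(len)
        fam_rows[[length(fam_rows) + 1L]] <- tibble(
          family = paste0("marker_", g, "_", k), role = "marker", genus = g,
          aa_seq = fam$aa, nt_seq = fam$nt)
      }
    }
    if (spec$background_pool_size > 0) {
      for (k in seq_len(spec$background_pool_size)) {
        len <- resample1(seq(spec$marker_len_aa[1], spec$marker_len_aa[2]))
        fam <- draw_family_gene(len)
        fam_rows[[length(fam_rows) + 1L]] <- tibble(
          family = paste0("background_", k), role = "background",
          genus = NA_character_, aa_seq = fam$aa, nt_seq = fam$nt)
      }
    }
    families <- dplyr::bind_rows(fam_rows)
    genomes <- list()
    labels <- list()
    truth <- list()
    bg_idx <- which(families$role == "background")
    serial <- 0L
    for (g in genera) {
      marker_idx <- which(families$genus %in% g)
      for (p in seq_len(spec$phages_per_genus)) {
        serial <- serial + 1L
        id <- sprintf("phage%03d", serial)
        gene_idx <- c(marker_idx,
                      if (spec$background_genes_per_phage > 0)
                        sample(bg_idx, spec$background_genes_per_phage))
        gene_idx <- reshuffle(gene_idx)
        seq_parts <- character(0)
        offset <- 0L
        add <- function(s) {
          seq_parts[[length(seq_parts) + 1L]] <<- s
          offset <<- offset + nchar(s)
        }
        add(random_spacer(spec$spacer_len))
        for (fi in gene_idx) {
          add(INSULATOR)
          gene_nt <- mutate_gene(families$nt_seq[fi], spec$mutation_rate)
          start0 <- offset
          add(gene_nt)
          truth[[length(truth) + 1L]] <- tibble(
            genome_id = id, start = start0, end = offset, strand = "+",
            family = families$family[fi], role = families$role[fi],
            genus = families$genus[fi])
          add(INSULATOR)
          add(random_spacer(spec$spacer_len))
        }
        genomes[[length(genomes) + 1L]] <- tibble(
          id = id, sequence = paste(seq_parts, collapse = ""),
          description = paste0("synthetic ", g, " phage"))
        labels[[length(labels) + 1L]] <- tibble(phage_id = id, genus = g)
      }
    }
    list(genomes = dplyr::bind_rows(genomes),
         labels = dplyr::bind_rows(labels),
         truth = dplyr::bind_rows(truth),
         families = families[, c("family", "role", "genus", "aa_seq")],
         spec = spec)
  })
}

#' Purity of a clustering against the planted marker families
#'
#' Matches called genes to planted marker genes by coordinates (forward
#' strand, exact span), looks up each matched gene's cluster, and computes
#' `purity = sum over clusters of the modal family count / total planted
#' marker genes`. Background genes are excluded. Planted genes that were not
#' recovered or not clustered count toward the denominator only, so a lossy
#' pipeline cannot inflate purity. Splitting one family across clusters does
#' not reduce purity; merging two families does.
#'
#' @param membership Tibble (`protein_id`, `cluster`) or (`protein_id`,
#'   `cluster_id`) from clustering.
#' @param genes Gene-call tibble with coordinates ([find_orfs()] output).
#' @param truth Ground-truth tibble from [generate_corpus()].
#' @return Purity in [0, 1].
#' @export
corpus_truth_purity <- function(membership, genes, truth) {
  if (nrow(membership) == 0) abort("empty clustering")
  cl_col <- if ("cluster" %in% names(membership)) "cluster" else "cluster_id"
  # score only genomes the clustering actually saw (e.g. the training split)
  seen <- unique(genes$genome_id[genes$protein_id %in% membership$protein_id])
  markers <- truth[truth$role == "marker" & truth$genome_id %in% seen, ]
  if (nrow(markers) == 0) abort("no planted marker genes in the clustered genomes")
  matched <- dplyr::inner_join(
    markers, genes[genes$strand == "+",
                   c("genome_id", "start", "end", "protein_id")],
    by = c("genome_id", "start", "end"))
  matched <- dplyr::left_join(matched,
                              stats::setNames(membership[, c("protein_id", cl_col)],
                                              c("protein_id", "cluster")),
                              by = "protein_id")
  clustered <- matched[!is.na(matched$cluster), ]
  if (nrow(clustered) == 0) return(0)
  modal <- clustered |>
    dplyr::count(.data$cluster, .data$family) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(modal = max(.data$n), .groups = "drop")
  sum(modal$modal) / nrow(markers)
}
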