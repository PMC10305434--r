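STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")

codon_map <- function() {
  if (is.null(the_cache$codon_map)) {
    gc <- Biostrings::GENETIC_CODE
    the_cache$codon_map <- stats::setNames(as.character(gc),
                                           chartr("U", "T", names(gc)))
  }
  the_cache$codon_map
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences over `A`, `C`, `G`, `T`, `N`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

#' Translate a coding DNA sequence
#'
#' Uses the bacterial/viral genetic code (translation table 11 shares its
#' codon-to-residue assignments with the standard table; the difference is
#' only in which codons may initiate). The terminal stop codon, if present,
#' is dropped from the product. An internal stop codon is an error, as is a
#' length not divisible by 3 or a codon that cannot be translated (e.g. one
#' containing `N`).
#'
#' @param nt Coding DNA string (single string).
#' @param as_start Render a leading `GTG`/`TTG` start codon as `M`?
#' @return Protein string.
#' @examples
#' translate_cds("ATGAAATAA")          # "MK"
#' translate_cds("GTGGCA", as_start = TRUE)  # "MA"
#' @export
translate_cds <- function(nt, as_start = FALSE) {
  stopifnot(is.character(nt), length(nt) == 1)
  nt <- toupper(nt)
  n <- nchar(nt)
  if (n %% 3 != 0) abort("coding sequence length not divisible by 3")
  if (n == 0) return("")
  pos <- seq(1L, n, 3L)
  codons <- substring(nt, pos, pos + 2L)
  n_cod <- length(codons)
  is_stop <- codons %in% STOP_CODONS
  if (any(is_stop[-n_cod])) {
    abort(paste0("internal stop codon at codon ", which(is_stop[-n_cod])[1]))
  }
  if (is_stop[n_cod]) codons <- codons[-n_cod]
  if (length(codons) == 0) return("")
  aa <- codon_map()[codons]
  if (anyNA(aa)) {
    abort(paste0("untranslatable codon '", codons[which(is.na(aa))[1]],
                 "' at codon ", which(is.na(aa))[1]))
  }
  if (as_start && codons[1] %in% c("GTG", "TTG")) aa[1] <- "M"
  paste(aa, collapse = "")
}

# Scan one strand of one sequence. Returns a data.frame of ORFs in local
# (scanned-strand) 1-based inclusive coordinates. An ORF runs from the first
# start codon after a terminator (or the sequence start) to the next in-frame
# terminator; stop codons terminate normally, codons containing N terminate
# the ORF at that point (the N codon plays the stop's role in the emitted
# coordinates).
scan_orfs_strand <- function(s, min_aa) {
  L <- nchar(s)
  out <- list()
  for (f in 0:2) {
    n_cod <- (L - f) %/% 3L
    if (n_cod < 2) next
    pos <- seq(f + 1L, by = 3L, length.out = n_cod)
    codons <- substring(s, pos, pos + 2L)
    is_term <- codons %in% STOP_CODONS | grepl("N", codons, fixed = TRUE)
    is_start <- codons %in% START_CODONS & !is_term
    terms <- which(is_term)
    seg_begin <- 1L
    for (t in terms) {
      if (t > seg_begin) {
        seg <- seq(seg_begin, t - 1L)
        starts <- seg[is_start[seg]]
        if (length(starts) > 0) {
          s_idx <- starts[1]
          aa_len <- t - s_idx
          if (aa_len >= min_aa) {
            aa_codons <- codons[seq(s_idx, t - 1L)]
            aa <- codon_map()[aa_codons]
            if (aa_codons[1] %in% c("GTG", "TTG")) aa[1] <- "M"
            out[[length(out) + 1L]] <- data.frame(
              s1 = pos[s_idx], e1 = pos[t] + 2L,
              aa_seq = paste(aa, collapse = ""),
              stringsAsFactors = FALSE
            )
          }
        }
      }
      seg_begin <- t + 1L
    }
  }
  if (length(out) == 0) {
    return(data.frame(s1 = integer(0), e1 = integer(0),
                      aa_seq = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Find open reading frames in phage genomes
#'
#' A deterministic six-frame maximal-ORF scanner: in each frame, an ORF is
#' the span from the first start codon (`ATG`/`GTG`/`TTG`) after a stop (or
#' the sequence start) to the next in-frame stop, stop codon included in the
#' coordinates but not in the translation. Leading `GTG`/`TTG` is rendered
#' `M`. Only ORFs of at least `min_aa` residues are reported. Reverse-strand
#' calls are reported in forward-strand coordinates with strand `-`. Calls
#' are sorted by (start, end, strand) and numbered `<genome_id>_<serial>`.
#'
#' @param genomes Genome tibble from [read_genomes()] (columns `id`,
#'   `sequence`), or any tibble with those columns.
#' @param min_aa Minimum protein length in residues (default 30).
#' @return A tibble with columns `protein_id`, `genome_id`, `start`, `end`
#'   (0-based half-open, forward strand), `strand`, `nt_seq` (coding
#'   orientation, terminator included), `aa_seq`.
#' @export
find_orfs <- function(genomes, min_aa = 30L) {
  stopifnot(all(c("id", "sequence") %in% names(genomes)))
  per_genome <- lapply(seq_len(nrow(genomes)), function(i) {
    s <- toupper(genomes$sequence[i])
    L <- nchar(s)
    fwd <- scan_orfs_strand(s, min_aa)
    rc <- revcomp(s)
    rev <- scan_orfs_strand(rc, min_aa)
    calls <- rbind(
      if (nrow(fwd) > 0) data.frame(start = fwd$s1 - 1L, end = fwd$e1,
                                    strand = "+", aa_seq = fwd$aa_seq,
                                    nt_seq = substring(s, fwd$s1, fwd$e1),
                                    stringsAsFactors = FALSE),
      if (nrow(rev) > 0) data.frame(start = L - rev$e1, end = L - rev$s1 + 1L,
                                    strand = "-", aa_seq = rev$aa_seq,
                                    nt_seq = substring(rc, rev$s1, rev$e1),
                                    stringsAsFactors = FALSE)
    )
    if (is.null(calls) || nrow(calls) == 0) return(NULL)
    ord <- order(calls$start, calls$end, calls$strand)
    calls <- calls[ord, , drop = FALSE]
    calls$genome_id <- genomes$id[i]
    calls$protein_id <- paste0(genomes$id[i], "_", seq_len(nrow(calls)))
    calls
  })
  per_genome <- per_genome[!vapply(per_genome, is.null, logical(1))]
  if (length(per_genome) == 0) {
    return(tibble(protein_id = character(0), genome_id = character(0),
                  start = integer(0), end = integer(0), strand = character(0),
                  nt_seq = character(0), aa_seq = character(0)))
  }
  out <- do.call(rbind, per_genome)
  as_tibble(out[, c("protein_id", "genome_id", "start", "end", "strand",
                    "nt_seq", "aa_seq")])
}

#' Export gene calls as GFF3
#'
#' Writes CDS features with 1-based inclusive coordinates per the GFF3
#' specification.
#'
#' @param genes Gene-call tibble from [find_orfs()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             paste(genes$genome_id, "phagehost", "CDS",
                   genes$start + 1L, genes$end, ".", genes$strand, "0",
                   paste0("ID=", genes$protein_id),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
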