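IUPAC_DNA <- c("A", "C", "G", "T", "U", "N",
               "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

fasta_wrap <- function(x, width = 70L) {
  unlist(lapply(x, function(s) {
    if (!nzchar(s)) return("")
    substring(s, seq(1L, nchar(s), width), pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s)))
  }), use.names = FALSE)
}

split_header <- function(headers) {
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  list(id = id, description = desc)
}

read_fasta_tbl <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort(paste0("not FASTA-parseable: ", path, " (", conditionMessage(e), ")")))
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  h <- split_header(names(set))
  tibble(id = h$id, sequence = unname(as.character(set)),
         description = h$description)
}

#' Read phage genome sequences from a FASTA file
#'
#' The header token before the first whitespace becomes the record id; the
#' remainder is kept as a free-text description. Sequences are upper-cased,
#' `U` is mapped to `T`, and IUPAC ambiguity codes other than `A`/`C`/`G`/`T`
#' are normalized to `N`. Characters outside the IUPAC DNA alphabet are an
#' error, as are duplicate ids and empty files.
#'
#' @param path Path to a FASTA file with one record per phage.
#' @return A tibble with columns `id`, `sequence`, `description`.
#' @export
read_genomes <- function(path) {
  tbl <- read_fasta_tbl(path)
  tbl$sequence <- toupper(tbl$sequence)
  dup <- tbl$id[duplicated(tbl$id)]
  if (length(dup) > 0) abort(paste0("duplicate id ", dup[1]))
  bad_pattern <- paste0("[^", paste(IUPAC_DNA, collapse = ""), "]")
  for (i in seq_len(nrow(tbl))) {
    hit <- regexpr(bad_pattern, tbl$sequence[i])
    if (hit > 0) {
      abort(paste0("non-IUPAC character '",
                   substr(tbl$sequence[i], hit, hit),
                   "' in record ", tbl$id[i], " at position ", hit))
    }
  }
  # U -> T, then fold ambiguity codes other than ACGT into N
  s <- chartr("U", "T", tbl$sequence)
  s <- gsub("[RYSWKMBDHV]", "N", s)
  tbl$sequence <- s
  if (any(!nzchar(tbl$sequence))) {
    abort(paste0("empty sequence for id ",
                 tbl$id[which(!nzchar(tbl$sequence))[1]]))
  }
  tbl
}

#' Write genome records to FASTA
#'
#' @param genomes Tibble with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genomes <- function(genomes, path) {
  stopifnot(all(c("id", "sequence") %in% names(genomes)))
  desc <- if ("description" %in% names(genomes)) genomes$description else ""
  header <- ifelse(nzchar(desc), paste(genomes$id, desc), genomes$id)
  lines <- unlist(Map(function(h, s) c(paste0(">", h), fasta_wrap(s)),
                      header, genomes$sequence), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' Intended both for the package's own gene-caller output and as an escape
#' hatch for externally predicted proteins (ids are expected to follow the
#' `genomeid_serial` convention so proteins can be attributed to genomes).
#' A single trailing `*` (stop) is stripped; internal `*` is an error.
#'
#' @param path Path to a protein FASTA file.
#' @return A tibble with columns `protein_id`, `aa_seq`, `description`.
#' @export
read_proteins <- function(path) {
  tbl <- read_fasta_tbl(path)
  dup <- tbl$id[duplicated(tbl$id)]
  if (length(dup) > 0) abort(paste0("duplicate id ", dup[1]))
  aa <- toupper(tbl$sequence)
  aa <- sub("\\*$", "", aa)
  if (any(grepl("*", aa, fixed = TRUE))) {
    abort(paste0("internal stop '*' in protein ",
                 tbl$id[which(grepl("*", aa, fixed = TRUE))[1]]))
  }
  validate_protein(aa, "protein sequence")
  tibble(protein_id = tbl$id, aa_seq = aa, description = tbl$description)
}

#' Write protein sequences to FASTA
#'
#' Accepts either a protein tibble (`protein_id`, `aa_seq`) or a gene-call
#' tibble from [find_orfs()].
#'
#' @param proteins Tibble with `protein_id` and `aa_seq` columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_proteins <- function(proteins, path) {
  stopifnot(all(c("protein_id", "aa_seq") %in% names(proteins)))
  lines <- unlist(Map(function(h, s) c(paste0(">", h), fasta_wrap(s)),
                      proteins$protein_id, proteins$aa_seq), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}
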