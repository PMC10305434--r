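#' Alignment scoring configuration
#'
#' Bundles the substitution matrix and affine gap penalties used everywhere a
#' protein pair is aligned: deduplication, similarity-graph construction, and
#' assignment of novel gene products to frozen clusters. Defaults follow the
#' classic `blastp` setup: BLOSUM62 with gap open 11 and gap extension 1
#' (a gap of length L costs `11 + L`).
#'
#' @param matrix Name of the substitution matrix. Only `"BLOSUM62"` ships.
#' @param gap_open Gap opening penalty (positive integer).
#' @param gap_extend Gap extension penalty per gapped position (positive
#'   integer). The first position of a gap pays `gap_open + gap_extend`.
#' @return An object of class `align_config`.
#' @export
align_config <- function(matrix = "BLOSUM62", gap_open = 11L, gap_extend = 1L) {
  if (!identical(matrix, "BLOSUM62")) {
    abort("only the BLOSUM62 substitution matrix is available")
  }
  structure(
    list(matrix = matrix, gap_open = as.integer(gap_open),
         gap_extend = as.integer(gap_extend)),
    class = "align_config"
  )
}

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V")

# 26x26 integer lookup over A-Z. Standard residues score per BLOSUM62; every
# other letter (X, B, Z, J, O, U, ...) scores the matrix's worst case, -4.
score_matrix26 <- function(config = align_config()) {
  key <- "blosum62_26"
  if (!is.null(the_cache[[key]])) {
    return(the_cache[[key]])
  }
  e <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = e)
  b62 <- e$BLOSUM62
  m <- matrix(-4L, 26L, 26L, dimnames = list(LETTERS, LETTERS))
  m[AA_STANDARD, AA_STANDARD] <- as.integer(b62[AA_STANDARD, AA_STANDARD])
  the_cache[[key]] <- m
  m
}

validate_protein <- function(x, what = "protein sequence") {
  bad <- grepl("[^A-Z]", x)
  if (any(bad)) {
    abort(paste0(what, " contains characters outside A-Z (first offender: ",
                 x[which(bad)[1]], ")"))
  }
  invisible(x)
}
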