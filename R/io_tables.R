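normalize_genus <- function(x) {
  x <- trimws(x)
  paste0(toupper(substr(x, 1, 1)), tolower(substring(x, 2)))
}

#' Read a phage-to-host-genus label table
#'
#' A two-column tab-separated file `phage_id<TAB>genus`, one row per
#' (phage, genus) pair; a phage labelled with several admissible host genera
#' appears on several rows. A header line is detected by the literal token
#' `phage_id`. Genus names are case-normalized (capitalized first letter,
#' rest lower). Duplicate pairs are collapsed.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `phage_id`, `genus`.
#' @export
read_host_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("empty label table: ", path))
  start <- if (grepl("phage_id", lines[1], fixed = TRUE)) 2L else 1L
  if (start > length(lines)) abort(paste0("label table has a header but no rows: ", path))
  parts <- strsplit(lines[seq(start, length(lines))], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2)) {
    bad <- which(nfield != 2)[1]
    abort(paste0("malformed row at line ", bad + start - 1L,
                 ": expected 2 tab-separated columns, got ", nfield[bad]))
  }
  out <- tibble(
    phage_id = vapply(parts, `[[`, character(1), 1L),
    genus = normalize_genus(vapply(parts, `[[`, character(1), 2L))
  )
  dplyr::distinct(out)
}

#' Write a host label table
#'
#' @param labels Tibble with columns `phage_id`, `genus`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_host_table <- function(labels, path) {
  stopifnot(all(c("phage_id", "genus") %in% names(labels)))
  readr::write_tsv(labels[, c("phage_id", "genus")], path)
  invisible(path)
}

#' Write a feature matrix as TSV
#'
#' Header row is `phage_id` followed by the cluster column ids; one row per
#' phage with integer counts. [read_feature_matrix()] round-trips exactly.
#'
#' @param m Integer matrix with phage ids as rownames and cluster column ids
#'   as colnames.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_feature_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  tbl <- as_tibble(m, rownames = "phage_id")
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read a feature matrix from TSV
#'
#' @param path Path written by [write_feature_matrix()].
#' @return Integer matrix with phage rownames and cluster colnames.
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    phage_id = readr::col_character(), .default = readr::col_integer()
  ))
  if (!"phage_id" %in% names(tbl)) abort("feature matrix TSV lacks a phage_id column")
  m <- as.matrix(tbl[, setdiff(names(tbl), "phage_id"), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- tbl$phage_id
  m
}

#' Write a train/test split as TSV
#'
#' Two columns: `phage_id` and `partition` (`train` or `test`).
#'
#' @param split A [split_corpus()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "corpus_split"))
  tbl <- tibble(
    phage_id = c(split$train_ids, split$test_ids),
    partition = rep(c("train", "test"),
                    c(length(split$train_ids), length(split$test_ids)))
  )
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read a train/test split written by [write_split()]
#'
#' @param path Path to the split TSV.
#' @return A `corpus_split` object (seed and fraction are not recorded in the
#'   file and are returned as `NA`).
#' @export
read_split <- function(path) {
  tbl <- readr::read_tsv(path, col_types = "cc")
  stopifnot(all(c("phage_id", "partition") %in% names(tbl)))
  new_corpus_split(tbl$phage_id[tbl$partition == "train"],
                   tbl$phage_id[tbl$partition == "test"],
                   seed = NA_integer_, fraction = NA_real_)
}
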