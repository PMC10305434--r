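#' Select the host genera with the most phages
#'
#' Ranks genera by the number of distinct phages labelled with them (a phage
#' counts once per genus it carries) and returns the top `n`. Ties are broken
#' alphabetically for reproducibility. Phages labelled only with unselected
#' genera are expected to be discarded by the caller.
#'
#' @param labels Host label tibble (`phage_id`, `genus`).
#' @param n Number of genera to keep (>= 1). If `n` exceeds the number of
#'   distinct genera, all genera are returned with a warning.
#' @return Character vector of genus names, most phage-rich first.
#' @export
select_top_genera <- function(labels, n) {
  stopifnot(n >= 1)
  counts <- labels |>
    dplyr::distinct(.data$phage_id, .data$genus) |>
    dplyr::count(.data$genus, name = "n_phages") |>
    dplyr::arrange(dplyr::desc(.data$n_phages), .data$genus)
  if (n > nrow(counts)) {
    warn(paste0("requested ", n, " genera but only ", nrow(counts),
                " are present; returning all"))
    n <- nrow(counts)
  }
  counts$genus[seq_len(n)]
}

new_corpus_split <- function(train_ids, test_ids, seed, fraction) {
  structure(
    list(train_ids = train_ids, test_ids = test_ids,
         seed = seed, fraction = fraction),
    class = "corpus_split"
  )
}

#' @export
print.corpus_split <- function(x, ...) {
  cat("<corpus_split> ", length(x$train_ids), " train / ",
      length(x$test_ids), " test (fraction ", x$fraction,
      ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Seeded random train/test split of a phage corpus
#'
#' Deterministic for a fixed seed. The train size is `round(fraction * n)`.
#' With stratification, phages are grouped by their first (alphabetical)
#' genus and train slots are allocated by the largest-remainder method, so
#' every stratum's train share is within one phage of `fraction` while the
#' total still equals `round(fraction * n)`.
#'
#' @param phage_ids Character vector of phage ids (>= 2).
#' @param fraction Train proportion in (0, 1); default 0.8.
#' @param seed Integer seed (required).
#' @param labels Host label tibble; required when `stratify = TRUE`.
#' @param stratify Stratify by genus? Off by default (plain random sampling).
#' @return A `corpus_split` with `train_ids`, `test_ids`, `seed`, `fraction`.
#' @export
split_corpus <- function(phage_ids, fraction = 0.8, seed, labels = NULL,
                         stratify = FALSE) {
  stopifnot(fraction > 0, fraction < 1)
  phage_ids <- unique(phage_ids)
  n <- length(phage_ids)
  if (n < 2) abort("need at least 2 phages to split")
  n_train <- round(fraction * n)
  if (n_train == 0 || n_train == n) {
    abort("fraction yields an empty train or test partition")
  }
  train <- withr::with_seed(seed, {
    if (!stratify) {
      sample(phage_ids, n_train)
    } else {
      if (is.null(labels)) abort("stratified split needs a label table")
      stratum <- labels |>
        dplyr::filter(.data$phage_id %in% phage_ids) |>
        dplyr::group_by(.data$phage_id) |>
        dplyr::summarise(stratum = min(.data$genus), .groups = "drop")
      missing <- setdiff(phage_ids, stratum$phage_id)
      if (length(missing) > 0) {
        stratum <- dplyr::bind_rows(
          stratum, tibble(phage_id = missing, stratum = "~unlabelled"))
      }
      groups <- split(stratum$phage_id, stratum$stratum)
      groups <- groups[order(names(groups))]
      sizes <- vapply(groups, length, integer(1))
      base <- floor(fraction * sizes)
      remainder <- fraction * sizes - base
      extra <- n_train - sum(base)
      if (extra > 0) {
        take <- order(-remainder, names(groups))[seq_len(extra)]
        base[take] <- base[take] + 1L
      }
      unlist(Map(function(ids, k) sample(ids, k), groups, base),
             use.names = FALSE)
    }
  })
  new_corpus_split(sort(train), sort(setdiff(phage_ids, train)),
                   seed = as.integer(seed), fraction = fraction)
}
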