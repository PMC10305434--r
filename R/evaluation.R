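#' Per-genus confusion counts for multi-label host predictions
#'
#' For each phage in the universe: TP if the genus is both predicted and
#' true, FP if predicted only, FN if true only, TN otherwise.
#'
#' @param predictions Tibble (`phage_id`, `genus`) of predicted admissible
#'   hosts (phages with empty predictions simply have no rows).
#' @param truth Tibble (`phage_id`, `genus`) of known hosts.
#' @param genus Genus to score.
#' @param phage_ids The phage universe. Defaults to the distinct ids in
#'   `truth`. Predictions or truth for phages outside the universe are an
#'   error.
#' @return A one-row tibble `genus`, `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(predictions, truth, genus,
                             phage_ids = unique(truth$phage_id)) {
  offenders <- unique(c(setdiff(predictions$phage_id, phage_ids),
                        setdiff(truth$phage_id, phage_ids)))
  if (length(offenders) > 0) {
    abort(paste0("phage ids outside the evaluation universe: ",
                 paste(head(offenders, 5), collapse = ", ")))
  }
  pred_pos <- phage_ids %in% predictions$phage_id[predictions$genus == genus]
  true_pos <- phage_ids %in% truth$phage_id[truth$genus == genus]
  tibble(
    genus = genus,
    tp = sum(pred_pos & true_pos),
    tn = sum(!pred_pos & !true_pos),
    fp = sum(pred_pos & !true_pos),
    fn = sum(!pred_pos & true_pos)
  )
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `TPR = TP / (TP + FN)`, specificity `TNR = TN / (TN + FP)`,
#' informedness `BM = TPR + TNR - 1` (Youden's J), and accuracy
#' `(TP + TN) / total`. A metric whose denominator is zero is undefined and
#' reported as `NA` — never silently 0 or 1 — and an undefined TPR or TNR
#' propagates into BM.
#'
#' @param confusion A tibble or list with fields `tp`, `tn`, `fp`, `fn`
#'   (vectorized: a multi-row tibble yields one metrics row per input row).
#' @return A tibble with columns `sensitivity`, `specificity`,
#'   `informedness`, `accuracy` appended to the counts.
#' @export
confusion_metrics <- function(confusion) {
  cf <- as_tibble(confusion[c("tp", "tn", "fp", "fn")])
  if ("genus" %in% names(confusion)) cf <- dplyr::bind_cols(confusion["genus"], cf)
  stopifnot(all(cf$tp >= 0, cf$tn >= 0, cf$fp >= 0, cf$fn >= 0))
  total <- cf$tp + cf$tn + cf$fp + cf$fn
  if (any(total == 0)) abort("all confusion counts are zero")
  p <- cf$tp + cf$fn
  n <- cf$tn + cf$fp
  tpr <- ifelse(p > 0, cf$tp / p, NA_real_)
  tnr <- ifelse(n > 0, cf$tn / n, NA_real_)
  dplyr::mutate(cf,
                sensitivity = tpr,
                specificity = tnr,
                informedness = tpr + tnr - 1,
                accuracy = (cf$tp + cf$tn) / total)
}

new_eval_report <- function(per_genus, n_test) {
  aggregate_accuracy <- sum(per_genus$tp + per_genus$tn) /
    sum(per_genus$tp + per_genus$tn + per_genus$fp + per_genus$fn)
  structure(
    list(per_genus = per_genus, n_test = n_test,
         aggregate_accuracy = aggregate_accuracy),
    class = "phage_eval"
  )
}

#' Evaluate a trained suite on a held-out test set
#'
#' Predicts admissible hosts for every test phage and scores each genus
#' separately (TP/TN/FP/FN plus sensitivity, specificity, informedness and
#' accuracy), mirroring a per-genus benchmark table. The aggregate accuracy
#' is `sum(TP + TN) / sum(TP + TN + FP + FN)` over all genus rows.
#'
#' @param suite A `host_tree_suite`.
#' @param test_matrix Feature matrix of test phages (columns must match the
#'   suite).
#' @param truth Host label tibble for the test phages.
#' @param decision_threshold See [predict_hosts()].
#' @return An object of class `phage_eval` with `per_genus` (tibble),
#'   `n_test`, and `aggregate_accuracy`.
#' @export
evaluate_suite <- function(suite, test_matrix, truth,
                           decision_threshold = 0.5) {
  stopifnot(inherits(suite, "host_tree_suite"))
  if (nrow(test_matrix) == 0) abort("empty test set")
  predictions <- predict_hosts(test_matrix, suite,
                               decision_threshold = decision_threshold)
  phage_ids <- rownames(test_matrix)
  truth <- truth[truth$phage_id %in% phage_ids, ]
  per_genus <- dplyr::bind_rows(lapply(suite$genera, function(g) {
    confusion_counts(predictions, truth, g, phage_ids = phage_ids)
  })) |> confusion_metrics()
  rep <- new_eval_report(per_genus, n_test = length(phage_ids))
  rep$predictions <- predictions
  rep
}

#' @export
print.phage_eval <- function(x, ...) {
  cat("<phage_eval> ", nrow(x$per_genus), " genera on ", x$n_test,
      " test phages; aggregate accuracy ",
      sprintf("%.4f", x$aggregate_accuracy), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.phage_eval <- function(x, ...) x$per_genus

#' @exportS3Method generics::glance
glance.phage_eval <- function(x, ...) {
  tibble(
    n_test = x$n_test,
    n_genera = nrow(x$per_genus),
    aggregate_accuracy = x$aggregate_accuracy,
    mean_informedness = mean(x$per_genus$informedness, na.rm = TRUE),
    min_informedness = suppressWarnings(min(x$per_genus$informedness,
                                            na.rm = TRUE))
  )
}

#' Write an evaluation report
#'
#' TSV mirrors the per-genus benchmark layout (genus, TP, TN, FP, FN plus
#' the metrics block); JSON additionally records the test size and aggregate
#' accuracy.
#'
#' @param report A `phage_eval`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"` (default from the file extension).
#' @return The path, invisibly.
#' @export
write_eval_report <- function(report, path,
                              format = if (grepl("\\.json$", path)) "json" else "tsv") {
  stopifnot(inherits(report, "phage_eval"))
  if (format == "tsv") {
    readr::write_tsv(report$per_genus, path)
  } else {
    jsonlite::write_json(
      list(n_test = report$n_test,
           aggregate_accuracy = report$aggregate_accuracy,
           per_genus = report$per_genus),
      path, auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  invisible(path)
}

#' Informedness against per-genus phage count
#'
#' Scatter of each genus's informedness against the number of test phages
#' labelled with it — the more phages a genus has, the more credible its
#' prediction tends to be.
#'
#' @param object A `phage_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.phage_eval <- function(object, ...) {
  d <- dplyr::mutate(object$per_genus, n_phages = .data$tp + .data$fn)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_phages, y = .data$informedness)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = "test phages labelled with genus",
                  y = "informedness (TPR + TNR - 1)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.phage_eval
#' @param report A `phage_eval`.
#' @export
plot_informedness <- function(report, ...) autoplot.phage_eval(report, ...)
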