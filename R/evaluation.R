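# Classification metrics and reweighting diagnostics -------------------------

#' Precision, recall and F1 for one class
#'
#' One-vs-rest counting: `P = tp/(tp+fp)`, `R = tp/(tp+fn)`,
#' `F1 = 2PR/(P+R)`. Degenerate cases use the conventions P = 0 when the
#' class is never predicted, R = 0 when it never occurs, F1 = 0 when
#' P + R = 0, so comparisons stay well-defined on degenerate folds.
#'
#' @param predicted,truth Equal-length vectors of 0-based class labels.
#' @param class_index The class to score.
#' @return A named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(predicted, truth, class_index) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  if (length(truth) < 1L) stop("need at least one observation")
  tp <- sum(predicted == class_index & truth == class_index)
  fp <- sum(predicted == class_index & truth != class_index)
  fn <- sum(predicted != class_index & truth == class_index)
  P <- if (tp + fp == 0) 0 else tp / (tp + fp)
  R <- if (tp + fn == 0) 0 else tp / (tp + fn)
  F1 <- if (P + R == 0) 0 else 2 * P * R / (P + R)
  c(precision = P, recall = R, f1 = F1)
}

#' Per-class and macro-averaged classification metrics
#'
#' @param predicted,truth Equal-length 0-based label vectors.
#' @param class_count Number of classes.
#' @return A data.frame with one row per class plus a `"macro"` row.
#' @export
class_metrics <- function(predicted, truth, class_count) {
  rows <- t(vapply(seq_len(class_count) - 1L, function(cl)
    precision_recall_f1(predicted, truth, cl), numeric(3)))
  out <- data.frame(class = c(as.character(seq_len(class_count) - 1L),
                              "macro"),
                    precision = c(rows[, 1], mean(rows[, 1])),
                    recall = c(rows[, 2], mean(rows[, 2])),
                    f1 = c(rows[, 3], mean(rows[, 3])))
  rownames(out) <- NULL
  out
}

macro_f1 <- function(predicted, truth, class_count) {
  m <- class_metrics(predicted, truth, class_count)
  m$f1[m$class == "macro"]
}

#' Mean importance weight of clean versus corrupted source examples
#'
#' Formalizes the near-zero-weights diagnostic: with a known ground-truth
#' corruption mask, reports the mean learned weight over each group and
#' the gap `mean_clean - mean_corrupted`.
#'
#' @param C Importance-weight vector.
#' @param corruption_mask Logical vector, `TRUE` for corrupted examples;
#'   both groups must be nonempty.
#' @return A list with `mean_clean`, `mean_corrupted`, `gap`.
#' @export
weight_separation <- function(C, corruption_mask) {
  if (length(C) != length(corruption_mask))
    stop("mask length must match the weight vector")
  if (!any(corruption_mask) || all(corruption_mask))
    stop("both clean and corrupted groups must be nonempty")
  mc <- mean(C[!corruption_mask])
  mx <- mean(C[corruption_mask])
  list(mean_clean = mc, mean_corrupted = mx, gap = mc - mx)
}

#' Weighted class-balance ratio of the source data
#'
#' Total importance weight of the positive source class divided by that of
#' the negative class. With uniform weights this reduces to the plain
#' count ratio; reweighting moving the ratio toward 1 indicates the
#' learned weights rebalance the two source classes.
#'
#' @param C Importance-weight vector.
#' @param source_labels Binary (0/1) source labels, same length.
#' @return Nonnegative scalar ratio.
#' @export
class_balance_ratio <- function(C, source_labels) {
  if (length(C) != length(source_labels))
    stop("labels must match the weight vector in length")
  wp <- sum(C[source_labels == 1L])
  wn <- sum(C[source_labels == 0L])
  if (wn == 0) stop("negative class carries zero total weight")
  if (wp == 0) stop("positive class carries zero total weight")
  wp / wn
}

#' Write a metrics report as CSV and JSON
#'
#' @param metrics A data.frame from [class_metrics()].
#' @param path_prefix Files `<prefix>.csv` and `<prefix>.json` are written.
#' @return The two paths, invisibly.
#' @export
write_metrics <- function(metrics, path_prefix) {
  csv <- paste0(path_prefix, ".csv")
  js <- paste0(path_prefix, ".json")
  utils::write.csv(metrics, csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(metrics, js, dataframe = "rows", digits = NA)
  invisible(c(csv, js))
}
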