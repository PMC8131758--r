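#' Confusion counts (TP/FP/FN) per class
#'
#' For each of the six classes, TP is the number of objects of that class
#' predicted as that class, FP the number of objects of other classes
#' predicted as it, and FN the number of objects of that class predicted
#' otherwise. An `UNKNOWN` prediction is never a true positive and counts as
#' a false negative for the object's truth class (it predicts no class, so
#' it contributes no FP). `UNKNOWN` is rejected as a truth label.
#'
#' Conservation holds by construction: the TP and FN columns sum to the
#' number of evaluated objects, and per class `TP + FN` equals the truth
#' count.
#'
#' @param predictions Character vector of predicted labels (six classes or
#'   `"UNKNOWN"`).
#' @param truth Character vector of truth labels (six classes only).
#' @param dataset Tag recorded with the counts (e.g. "train", "test").
#' @return Data frame (class `confusion_counts`) with columns `dataset`,
#'   `class`, `tp`, `fp`, `fn`.
#' @export
confusion_counts <- function(predictions, truth, dataset = "test") {
  if (length(predictions) != length(truth))
    stop("predictions and truth must have equal length")
  assert_class_label(truth, allow_unknown = FALSE)
  assert_class_label(predictions, allow_unknown = TRUE)
  classes <- mn_classes()
  tp <- fp <- fn <- integer(length(classes))
  for (i in seq_along(classes)) {
    k <- classes[i]
    tp[i] <- sum(predictions == k & truth == k)
    fp[i] <- sum(predictions == k & truth != k)
    fn[i] <- sum(truth == k & predictions != k)
  }
  out <- data.frame(dataset = dataset, class = classes, tp = tp, fp = fp,
                    fn = fn, stringsAsFactors = FALSE)
  class(out) <- c("confusion_counts", "data.frame")
  out
}

#' Precision, recall and F1 per class, in percent
#'
#' precision = 100 TP / (TP + FP), recall = 100 TP / (TP + FN),
#' F1 = 2 P R / (P + R). A metric with a zero denominator is reported as
#' `NA` (undefined) rather than 0, so that undefined classes cannot silently
#' distort weighted averages. Unrounded values are returned; use
#' `round(x, 1)` for tabulation at the conventional 1-decimal precision.
#'
#' @param counts A [confusion_counts()] data frame (columns `class`, `tp`,
#'   `fp`, `fn`; a `dataset` column is carried through if present).
#' @return Data frame (class `class_metrics`) with columns `class`,
#'   `truth_count`, `precision`, `recall`, `f1` (percent).
#' @export
compute_class_metrics <- function(counts) {
  stopifnot(all(c("class", "tp", "fp", "fn") %in% names(counts)))
  if (any(counts$tp < 0 | counts$fp < 0 | counts$fn < 0))
    stop("counts must be non-negative")
  p <- ifelse(counts$tp + counts$fp > 0,
              100 * counts$tp / (counts$tp + counts$fp), NA_real_)
  r <- ifelse(counts$tp + counts$fn > 0,
              100 * counts$tp / (counts$tp + counts$fn), NA_real_)
  f1 <- ifelse(!is.na(p) & !is.na(r) & (p + r) > 0, 2 * p * r / (p + r),
               NA_real_)
  out <- data.frame(class = counts$class,
                    truth_count = counts$tp + counts$fn,
                    precision = p, recall = r, f1 = f1,
                    stringsAsFactors = FALSE)
  if ("dataset" %in% names(counts)) out <- cbind(dataset = counts$dataset, out)
  class(out) <- c("class_metrics", "data.frame")
  out
}

#' Truth-count-weighted average F1
#'
#' The overall accuracy of a multi-class model is summarized as the mean of
#' the per-class F1 scores weighted by each class's truth count (TP + FN),
#' computed from unrounded per-class values.
#'
#' @param metrics A [compute_class_metrics()] data frame.
#' @param truth_counts Optional weights; defaults to `metrics$truth_count`.
#' @return Weighted mean F1 in percent (unrounded scalar).
#' @export
weighted_average_metrics <- function(metrics, truth_counts = NULL) {
  if (is.null(truth_counts)) truth_counts <- metrics$truth_count
  if (length(truth_counts) != nrow(metrics))
    stop("one truth count per class is required")
  if (sum(truth_counts) == 0) stop("total truth count is zero")
  if (any(is.na(metrics$f1)))
    stop("cannot average undefined (NA) F1 values")
  sum(metrics$f1 * truth_counts) / sum(truth_counts)
}

#' Reference confusion counts of a published six-class MN classifier
#'
#' Per-class TP/FP/FN counts reported for a six-class micronucleus-assay
#' CNN evaluated on its training, validation and test splits (1,000 MONO,
#' 150 MONO_MN, 1,000 BN, 150 BN_MN, 350 POLY and 500 IRREG truth objects in
#' each of the validation and test splits). They serve as input for exact
#' metric accounting: [compute_class_metrics()] and
#' [weighted_average_metrics()] reproduce the published per-class
#' precision/recall/F1 table and the overall weighted accuracies from these
#' counts alone.
#'
#' @return Data frame with columns `dataset` (training/validation/testing),
#'   `class`, `tp`, `fp`, `fn`.
#' @export
reference_confusion_counts <- function() {
  path <- system.file("extdata", "reference_model_counts.csv",
                      package = "mnscore", mustWork = TRUE)
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("confusion_counts", "data.frame")
  out
}

#' Full metric table across datasets
#'
#' Convenience wrapper producing the class x dataset metric table (TP, FP,
#' FN, precision, recall, F1 rounded to 1 decimal) plus one weighted-average
#' row per dataset.
#'
#' @param counts A `confusion_counts` data frame covering one or more
#'   datasets.
#' @return Data frame in long layout.
#' @export
metrics_table <- function(counts) {
  stopifnot("dataset" %in% names(counts))
  out <- list()
  for (d in unique(counts$dataset)) {
    sub <- counts[counts$dataset == d, ]
    m <- compute_class_metrics(sub)
    tab <- data.frame(dataset = d, class = sub$class, tp = sub$tp,
                      fp = sub$fp, fn = sub$fn,
                      precision = round(m$precision, 1),
                      recall = round(m$recall, 1), f1 = round(m$f1, 1),
                      stringsAsFactors = FALSE)
    # classes an (early, weak) model never predicts have undefined precision;
    # average over the defined classes only, NA when none are defined
    ok <- !is.na(m$f1)
    w <- if (any(ok)) round(weighted_average_metrics(m[ok, , drop = FALSE]), 1)
         else NA_real_
    wavg <- data.frame(dataset = d, class = "weighted_average", tp = NA,
                       fp = NA, fn = NA, precision = NA, recall = NA,
                       f1 = w, stringsAsFactors = FALSE)
    out[[d]] <- rbind(tab, wavg)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
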