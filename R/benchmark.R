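# Benchmarking: confusion matrix, sensitivity/specificity/accuracy, the
# empirical ROC curve with trapezoid AUC, fold enrichment, and
# method-comparison tables over labeled disease/control gene sets.

#' Construct a benchmark label set
#'
#' @param positives character vector of known disease genes.
#' @param negatives character vector of control genes.
#' @return object of class `benchmark_labels` with disjoint, non-empty
#'   `positives` and `negatives`.
#' @export
benchmark_labels <- function(positives, negatives) {
  positives <- unique(normalize_id(positives))
  negatives <- unique(normalize_id(negatives))
  if (length(positives) == 0L || length(negatives) == 0L) {
    stop("both positives and negatives must be non-empty", call. = FALSE)
  }
  clash <- intersect(positives, negatives)
  if (length(clash) > 0L) {
    stop("labels overlap: ", paste(head(clash, 5L), collapse = ", "),
         call. = FALSE)
  }
  structure(list(positives = positives, negatives = negatives,
                 n_total = length(positives) + length(negatives)),
            class = "benchmark_labels")
}

#' Confusion matrix of a predicted-positive set
#'
#' Predictions outside the labeled universe are dropped with a warning.
#'
#' @param predicted_positive character vector of genes called positive.
#' @param labels a [benchmark_labels()].
#' @return object of class `confusion_matrix` (list with `tp`, `fp`, `tn`,
#'   `fn`).
#' @export
benchmark_confusion <- function(predicted_positive, labels) {
  stopifnot(inherits(labels, "benchmark_labels"))
  predicted_positive <- unique(normalize_id(predicted_positive))
  universe <- c(labels$positives, labels$negatives)
  outside <- setdiff(predicted_positive, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " predicted gene(s) outside the labeled universe dropped")
    predicted_positive <- intersect(predicted_positive, universe)
  }
  tp <- length(intersect(predicted_positive, labels$positives))
  fp <- length(intersect(predicted_positive, labels$negatives))
  structure(list(tp = tp, fp = fp,
                 fn = length(labels$positives) - tp,
                 tn = length(labels$negatives) - fp),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix: TP=%d FP=%d TN=%d FN=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Sensitivity, specificity and accuracy
#'
#' `sensitivity = tp/(tp+fn)`, `specificity = tn/(tn+fp)`,
#' `accuracy = (tp+tn)/(tp+fp+tn+fn)`. A metric with a zero denominator is
#' reported as `NA` rather than 0.
#'
#' @param matrix a `confusion_matrix`.
#' @return named numeric vector `c(sensitivity, specificity, accuracy)`.
#' @export
benchmark_metrics <- function(matrix) {
  stopifnot(inherits(matrix, "confusion_matrix"))
  with(matrix, c(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = if (tp + fp + tn + fn > 0) {
      (tp + tn) / (tp + fp + tn + fn)
    } else NA_real_))
}

#' Empirical ROC curve and AUC
#'
#' Sweeps the decision threshold over the distinct score values (ties are
#' grouped into a single threshold step, so the curve is order-independent),
#' calling a gene positive when `score >= threshold`. The curve runs from
#' (0, 0) to (1, 1) in true-positive rate versus false-positive rate; AUC is
#' computed by the trapezoid rule, which with grouped ties equals the
#' Mann-Whitney probability that a random positive outscores a random
#' negative (ties counting one half). Labeled genes without a score are
#' scored 0 with a warning; all-equal scores give the diagonal and AUC 0.5.
#'
#' @param scores named numeric vector, gene -> score (higher = more
#'   disease-like).
#' @param labels a [benchmark_labels()].
#' @return list: `points` (`data.frame` with `threshold`, `fpr`, `tpr`;
#'   threshold `Inf` for the (0,0) anchor) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(inherits(labels, "benchmark_labels"))
  universe <- c(labels$positives, labels$negatives)
  missing <- setdiff(universe, names(scores))
  if (length(missing) > 0L) {
    warning(length(missing), " labeled gene(s) without a score; scored as 0")
    scores <- c(scores, setNames(rep(0, length(missing)), missing))
  }
  s <- scores[universe]
  y <- universe %in% labels$positives
  np <- sum(y); nn <- sum(!y)
  thresholds <- sort(unique(as.numeric(s)), decreasing = TRUE)
  tpr <- numeric(length(thresholds)); fpr <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    called <- s >= thresholds[i]
    tpr[i] <- sum(called & y) / np
    fpr[i] <- sum(called & !y) / nn
  }
  points <- data.frame(threshold = c(Inf, thresholds),
                       fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + points$tpr[-1]) / 2)
  list(points = points, auc = auc)
}

#' Fold-enrichment ratio of a prediction
#'
#' Default (`"density"`): the disease-gene density among predicted positives
#' divided by the background density in the whole benchmark set,
#' `(tp / (tp + fp)) / (|positives| / |universe|)`. A label-independent
#' predictor has expected enrichment 1; predicting only true positives gives
#' the maximum, `|universe| / |positives|`. The `"sensitivity"` definition
#' is the literal proportion-of-disease-genes reading,
#' `tp / |positives|`. Returns `NA` if nothing was predicted.
#'
#' @param matrix a `confusion_matrix`.
#' @param labels a [benchmark_labels()].
#' @param definition `"density"` (default) or `"sensitivity"`.
#' @return numeric scalar (or `NA`).
#' @export
enrichment_ratio <- function(matrix, labels,
                             definition = c("density", "sensitivity")) {
  stopifnot(inherits(matrix, "confusion_matrix"),
            inherits(labels, "benchmark_labels"))
  definition <- match.arg(definition)
  n_pred <- matrix$tp + matrix$fp
  if (n_pred == 0L) return(NA_real_)
  if (definition == "density") {
    (matrix$tp / n_pred) / (length(labels$positives) / labels$n_total)
  } else {
    matrix$tp / length(labels$positives)
  }
}

#' Evaluate one predicted-positive set end to end
#'
#' @param predicted_positive character vector of genes called positive.
#' @param labels a [benchmark_labels()].
#' @param scores optional named score vector; when given, the empirical ROC
#'   and AUC are included.
#' @return object of class `benchmark_result`: `matrix`, `sensitivity`,
#'   `specificity`, `accuracy`, `enrichment`, and (optionally) `roc_points`,
#'   `auc`.
#' @export
benchmark_prediction <- function(predicted_positive, labels, scores = NULL) {
  cm <- benchmark_confusion(predicted_positive, labels)
  met <- benchmark_metrics(cm)
  out <- list(matrix = cm,
              sensitivity = met[["sensitivity"]],
              specificity = met[["specificity"]],
              accuracy = met[["accuracy"]],
              enrichment = enrichment_ratio(cm, labels))
  if (!is.null(scores)) {
    roc <- roc_curve(scores, labels)
    out$roc_points <- roc$points
    out$auc <- roc$auc
  }
  class(out) <- "benchmark_result"
  out
}

#' @export
print.benchmark_result <- function(x, ...) {
  print(x$matrix)
  cat(sprintf("  sensitivity %.3f, specificity %.3f, accuracy %.3f, enrichment %.2f-fold\n",
              x$sensitivity, x$specificity, x$accuracy, x$enrichment))
  if (!is.null(x$auc)) cat(sprintf("  AUC %.3f\n", x$auc))
  invisible(x)
}

#' Performance comparison table across methods
#'
#' One row per metric (accuracy, sensitivity, specificity, as percentages to
#' one decimal) and one column per method, in the layout of published
#' method-comparison tables. A method whose prediction set is empty of
#' labeled genes yields a column of `NA`.
#'
#' @param predictions named list: method name -> character vector of
#'   predicted-positive genes.
#' @param labels a [benchmark_labels()].
#' @return `data.frame` with a `metric` column plus one column per method.
#' @export
comparison_table <- function(predictions, labels) {
  stopifnot(length(predictions) >= 1L, !is.null(names(predictions)))
  cols <- lapply(predictions, function(pred) {
    pred <- suppressWarnings(
      intersect(normalize_id(pred), c(labels$positives, labels$negatives)))
    if (length(pred) == 0L) {
      return(c(NA_real_, NA_real_, NA_real_))
    }
    m <- benchmark_metrics(benchmark_confusion(pred, labels))
    round(100 * c(m[["accuracy"]], m[["sensitivity"]], m[["specificity"]]), 1)
  })
  out <- data.frame(metric = c("Accuracy (%)", "Sensitivity (%)",
                               "Specificity (%)"),
                    stringsAsFactors = FALSE)
  for (nm in names(predictions)) out[[nm]] <- cols[[nm]]
  out
}
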