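# Malformation classification from the Dice feature: C-SVC with polynomial
# kernel, plus the four confusion metrics.

#' Confusion counts from true and predicted labels
#'
#' @param truth,pred vectors of labels.
#' @param positive the positive-class label (malformed / patient group).
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion_counts <- function(truth, pred, positive = "malformed") {
  truth_pos <- truth == positive
  pred_pos <- pred == positive
  c(TP = sum(truth_pos & pred_pos), TN = sum(!truth_pos & !pred_pos),
    FP = sum(!truth_pos & pred_pos), FN = sum(truth_pos & !pred_pos))
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' (sensitivity) `TP/(TP+FN)` and specificity `TN/(TN+FP)`. A metric whose
#' denominator is zero is undefined: it is returned as `NA` with a warning,
#' never silently as 0.
#'
#' @param counts named vector with `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric vector of the four metrics.
#' @export
confusion_metrics <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  total <- tp + tn + fp + fn
  if (total < 1) stop("confusion counts are all zero")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined: zero denominator", what))
      return(NA_real_)
    }
    num / den
  }
  c(accuracy = (tp + tn) / total,
    precision = safe_div(tp, tp + fp, "precision"),
    recall = safe_div(tp, tp + fn, "recall"),
    specificity = safe_div(tn, tn + fp, "specificity"))
}

#' Fit the C-SVC malformation classifier on the Dice feature
#'
#' Fits a C-support vector classifier with polynomial kernel on the
#' one-dimensional Dice feature, with the malformed/patient group as the
#' positive class. Following the reference protocol the classifier is
#' evaluated on its own training data — a practice that is deliberately
#' preserved to quantify inter-group overlap, not generalization — and the
#' report therefore carries an explicit `in_sample = TRUE` flag.
#' Hyperparameters default to degree 3, cost 1, zero independent term and
#' kernel coefficient `1 / var(x)` (scaled by the feature variance).
#'
#' @param dsc_values numeric Dice values, one per subject.
#' @param labels class labels; must contain both classes.
#' @param positive positive-class label (default `"malformed"`).
#' @param degree,cost,coef0 polynomial-kernel hyperparameters.
#' @param gamma kernel coefficient; default `1 / var(dsc_values)`.
#' @return An object of class `chiasm_svc`: the fitted model plus a report
#'   with per-subject predictions, a decision-boundary description (sign
#'   changes of the decision function over the feature range), confusion
#'   counts, the four metrics and the `in_sample` flag.
#' @export
fit_svc <- function(dsc_values, labels, positive = "malformed",
                    degree = 3, cost = 1, coef0 = 0, gamma = NULL) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (length(dsc_values) != length(labels)) stop("length mismatch")
  negative <- setdiff(unique(labels), positive)
  if (length(negative) != 1L) stop("expected exactly two classes")
  y <- factor(labels, levels = c(negative, positive))
  x <- matrix(as.numeric(dsc_values), ncol = 1)
  if (is.null(gamma)) {
    vx <- stats::var(dsc_values)
    gamma <- if (vx > 0) 1 / vx else 1
  }
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "polynomial",
                    degree = degree, cost = cost, coef0 = coef0,
                    gamma = gamma, scale = FALSE)
  pred <- as.character(stats::predict(fit, x))
  counts <- confusion_counts(labels, pred, positive)
  metrics <- suppressWarnings(confusion_metrics(counts))
  # decision boundary: sign changes of the decision function on a fine grid
  grid <- seq(min(dsc_values) - 0.05, max(dsc_values) + 0.05, length.out = 2001)
  dv <- attr(stats::predict(fit, matrix(grid, ncol = 1),
                            decision.values = TRUE), "decision.values")[, 1]
  flips <- which(diff(sign(dv)) != 0)
  boundary <- (grid[flips] + grid[flips + 1]) / 2
  structure(list(model = fit, positive = positive,
                 dsc_values = as.numeric(dsc_values), labels = labels,
                 predicted = pred, boundary = boundary,
                 counts = counts, metrics = metrics, in_sample = TRUE,
                 hyperparameters = list(degree = degree, cost = cost,
                                        coef0 = coef0, gamma = gamma)),
            class = "chiasm_svc")
}

#' @export
print.chiasm_svc <- function(x, ...) {
  cat("C-SVC (polynomial kernel) on the Dice feature  [in-sample evaluation]\n")
  cat(sprintf("boundary (decision-function zero crossings): %s\n",
              if (length(x$boundary)) paste(sprintf("%.4f", x$boundary),
                                            collapse = ", ") else "none"))
  cat(sprintf("counts: TP=%d TN=%d FP=%d FN=%d\n", x$counts[["TP"]],
              x$counts[["TN"]], x$counts[["FP"]], x$counts[["FN"]]))
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  specificity %.4f\n",
              x$metrics[["accuracy"]], x$metrics[["precision"]],
              x$metrics[["recall"]], x$metrics[["specificity"]]))
  invisible(x)
}

#' Write a classifier report as JSON
#'
#' @param svc a `chiasm_svc`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_svc_report <- function(svc, path) {
  stopifnot(inherits(svc, "chiasm_svc"))
  report <- list(
    positive_class = svc$positive,
    in_sample = svc$in_sample,
    boundary = svc$boundary,
    labels = svc$labels,
    predicted = svc$predicted,
    dsc = svc$dsc_values,
    counts = as.list(svc$counts),
    metrics = as.list(svc$metrics),
    hyperparameters = svc$hyperparameters)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
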