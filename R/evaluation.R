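# Report surface: 3x3 confusion matrix, per-class sensitivity / precision /
# miss rate, overall accuracy, one-vs-rest ROC curves with trapezoid AUC,
# and a summary table in the style used for three-class EEG diagnosis
# studies (rows = methods, columns = sensitivity / precision / AUC /
# accuracy).

CLASS_NAMES <- c("MCI", "AD", "HC")

#' Three-class confusion matrix
#'
#' `counts[i, j]` is the number of subjects with true class `i` predicted as
#' class `j`, class order 1 = MCI, 2 = AD, 3 = HC.
#'
#' @param y_true,y_pred Integer label vectors of equal length with values in
#'   `{1, 2, 3}`.
#' @return Object of class `confusion_matrix3` with fields `counts` and `n`.
#' @export
#' @examples
#' confusion_matrix3(c(1, 2, 3), c(1, 2, 2))
confusion_matrix3 <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (!all(y_true %in% 1:3) || !all(y_pred %in% 1:3))
    stop("labels must be in {1, 2, 3}")
  counts <- table(factor(y_true, 1:3), factor(y_pred, 1:3))
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = list(true = CLASS_NAMES, pred = CLASS_NAMES))
  structure(list(counts = counts, n = length(y_true)),
            class = "confusion_matrix3")
}

#' @export
print.confusion_matrix3 <- function(x, ...) {
  cat("<confusion_matrix3> n =", x$n, "\n")
  print(x$counts)
  invisible(x)
}

#' Per-class sensitivity (recall)
#'
#' `TP / (TP + FN)`: the diagonal entry of the class row divided by the row
#' sum.
#'
#' @param cm A [confusion_matrix3()].
#' @param class Class label in `{1, 2, 3}`.
#' @return Fraction in `[0, 1]`.
#' @export
sensitivity <- function(cm, class) {
  stopifnot(inherits(cm, "confusion_matrix3"), class %in% 1:3)
  rs <- sum(cm$counts[class, ])
  if (rs == 0) stop("sensitivity undefined: no subjects with true class ", class)
  cm$counts[class, class] / rs
}

#' Per-class precision
#'
#' `TP / column-sum`: the diagonal entry of the predicted-class column
#' divided by the column sum.
#'
#' @inheritParams sensitivity
#' @return Fraction in `[0, 1]`.
#' @export
precision <- function(cm, class) {
  stopifnot(inherits(cm, "confusion_matrix3"), class %in% 1:3)
  cs <- sum(cm$counts[, class])
  if (cs == 0) stop("precision undefined: no predictions of class ", class)
  cm$counts[class, class] / cs
}

#' Overall accuracy
#'
#' Trace of the confusion matrix over the total count.
#'
#' @param cm A [confusion_matrix3()].
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix3"))
  if (cm$n == 0) stop("empty confusion matrix")
  sum(diag(cm$counts)) / cm$n
}

#' One-vs-rest ROC curve and AUC
#'
#' Sweeps thresholds over the class's score column (highest first). TPR =
#' TP/Y and FPR = FP/N; tied scores are grouped at a single threshold step
#' (standard staircase); AUC by the trapezoid rule.
#'
#' @param y_true Integer labels in `{1, 2, 3}`.
#' @param scores N x 3 score matrix, rows summing to 1.
#' @param class The positive class for the one-vs-rest reduction.
#' @return Object of class `roc_result` with `thresholds`, `fpr`, `tpr`,
#'   `auc` and `class`.
#' @export
roc_one_vs_rest <- function(y_true, scores, class) {
  stopifnot(class %in% 1:3, is.matrix(scores), ncol(scores) == 3,
            nrow(scores) == length(y_true))
  if (any(abs(rowSums(scores) - 1) > 1e-6))
    stop("score rows must sum to 1")
  pos <- y_true == class
  if (all(pos) || !any(pos))
    stop("degenerate ROC: need both positive and negative cases")
  s <- scores[, class]
  thr <- sort(unique(s), decreasing = TRUE)
  np <- sum(pos); nn <- sum(!pos)
  tp <- cumsum(vapply(thr, function(t) sum(pos & s == t), numeric(1)))
  fp <- cumsum(vapply(thr, function(t) sum(!pos & s == t), numeric(1)))
  structure(list(thresholds = c(Inf, thr),
                 fpr = c(0, fp / nn), tpr = c(0, tp / np),
                 auc = sum(diff(c(0, fp / nn)) *
                             (head(c(0, tp / np), -1) + tail(c(0, tp / np), -1)) / 2),
                 class = class),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> class %s (one-vs-rest), %d points, AUC = %.4f\n",
              CLASS_NAMES[x$class], length(x$fpr), x$auc))
  invisible(x)
}

#' Summarize a model's performance
#'
#' Emits per-class sensitivity, precision and miss rate (percent), overall
#' accuracy (percent), per-class one-vs-rest AUC and their macro average.
#' Percentages are reported to one decimal (half-up) by the print method;
#' the stored values are exact.
#'
#' @param cm A [confusion_matrix3()].
#' @param rocs List of three [roc_one_vs_rest()] results (classes 1..3), or
#'   `NULL` when no scores are available.
#' @param kind Model identifier string.
#' @return Object of class `evaluation_report`.
#' @export
summarize_performance <- function(cm, rocs = NULL, kind = "model") {
  sens <- vapply(1:3, function(cl) sensitivity(cm, cl), numeric(1))
  prec <- vapply(1:3, function(cl)
    tryCatch(precision(cm, cl), error = function(e) NA_real_), numeric(1))
  aucs <- if (is.null(rocs)) rep(NA_real_, 3)
          else vapply(rocs, function(r) r$auc, numeric(1))
  names(sens) <- names(prec) <- names(aucs) <- CLASS_NAMES
  structure(list(model = kind,
                 sensitivity_pct = 100 * sens,
                 precision_pct = 100 * prec,
                 miss_rate_pct = 100 * (1 - sens),
                 accuracy_pct = 100 * accuracy(cm),
                 auc = aucs,
                 macro_auc = mean(aucs),
                 confusion = cm),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  fmt <- function(v) paste(sprintf("%.1f", round_half_up(v, 1)), collapse = " / ")
  cat(sprintf("<evaluation_report> %s\n", x$model))
  cat("  sensitivity (MCI/AD/HC %): ", fmt(x$sensitivity_pct), "\n")
  cat("  precision   (MCI/AD/HC %): ", fmt(x$precision_pct), "\n")
  cat("  miss rate   (MCI/AD/HC %): ", fmt(x$miss_rate_pct), "\n")
  if (!anyNA(x$auc))
    cat(sprintf("  AUC (MCI/AD/HC): %s  macro %.3f\n",
                paste(sprintf("%.3f", x$auc), collapse = " / "), x$macro_auc))
  cat(sprintf("  accuracy: %.1f%%\n", round_half_up(x$accuracy_pct, 1)))
  invisible(x)
}

#' @export
as.data.frame.evaluation_report <- function(x, ...) {
  data.frame(model = x$model,
             sens_mci = x$sensitivity_pct[1], sens_ad = x$sensitivity_pct[2],
             sens_hc = x$sensitivity_pct[3],
             prec_mci = x$precision_pct[1], prec_ad = x$precision_pct[2],
             prec_hc = x$precision_pct[3],
             auc_macro = x$macro_auc, accuracy = x$accuracy_pct,
             row.names = NULL)
}

#' Evaluate predictions end to end
#'
#' Convenience wrapper: confusion matrix, three one-vs-rest ROC curves and
#' the summary report.
#'
#' @param y_true Integer labels.
#' @param pred Prediction list (`labels`, `scores`) from
#'   [predict.tdpsd_model()].
#' @param kind Model identifier for the report.
#' @return An `evaluation_report`.
#' @export
evaluate_predictions <- function(y_true, pred, kind = "model") {
  cm <- confusion_matrix3(y_true, pred$labels)
  rocs <- lapply(1:3, function(cl)
    tryCatch(roc_one_vs_rest(y_true, pred$scores, cl),
             error = function(e) NULL))
  if (any(vapply(rocs, is.null, logical(1)))) rocs <- NULL
  summarize_performance(cm, rocs, kind)
}
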