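#' Three-class confusion matrix
#'
#' Rows are truth, columns predictions, both in the reporting order
#' `Ideal`, `Investigate`, `Replan` (highest to lowest GPR).
#'
#' @param y_true,y_pred equal-length label vectors (factor or character
#'   over the levels in [gpr_levels]).
#' @return 3 x 3 integer matrix of class `confusion_matrix3`.
#' @export
confusion_matrix3 <- function(y_true, y_pred) {
  y_true <- as_gpr_factor(y_true)
  y_pred <- as_gpr_factor(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  disp <- rev(gpr_levels)  # Ideal, Investigate, Replan
  cm <- table(factor(as.character(y_true), levels = disp),
              factor(as.character(y_pred), levels = disp))
  cm <- matrix(as.integer(cm), 3L, 3L, dimnames = list(truth = disp,
                                                       predicted = disp))
  structure(cm, class = c("confusion_matrix3", "matrix", "array"))
}

#' Build a confusion matrix from printed counts
#'
#' Convenience constructor for entering a published 3 x 3 confusion matrix
#' directly (rows truth, columns predicted, order Ideal / Investigate /
#' Replan).
#'
#' @param counts 9 integers, row-major.
#' @return A `confusion_matrix3`.
#' @export
as_confusion_matrix3 <- function(counts) {
  stopifnot(length(counts) == 9L, all(counts >= 0))
  disp <- rev(gpr_levels)
  structure(matrix(as.integer(counts), 3L, 3L, byrow = TRUE,
                   dimnames = list(truth = disp, predicted = disp)),
            class = c("confusion_matrix3", "matrix", "array"))
}

cm_class_index <- function(cm, cls) {
  cls <- as.character(cls)
  i <- match(cls, rownames(cm))
  if (is.na(i)) stop("unknown class: ", cls, call. = FALSE)
  i
}

#' One-vs-all sensitivity
#'
#' `100 * TP / (TP + FN)` for the named class against the rest, where the
#' class's truth row supplies TP (diagonal) and FN (off-diagonal).
#'
#' @param cm a `confusion_matrix3`.
#' @param cls class name (`"Ideal"`, `"Investigate"` or `"Replan"`).
#' @param digits decimals to round to (2 matches the usual reporting);
#'   `NULL` for no rounding.
#' @return Sensitivity in percent.
#' @export
sensitivity_ova <- function(cm, cls, digits = 2) {
  i <- cm_class_index(cm, cls)
  tp <- cm[i, i]
  fn <- sum(cm[i, -i])
  if (tp + fn == 0)
    stop("sensitivity undefined: no truth samples of class ", cls,
         call. = FALSE)
  val <- 100 * tp / (tp + fn)
  if (is.null(digits)) val else round(val, digits)
}

#' One-vs-all specificity
#'
#' `100 * TN / (TN + FP)` for the named class against the rest: FP is the
#' class's prediction column off the diagonal, TN everything outside the
#' class's row and column.
#'
#' @inheritParams sensitivity_ova
#' @return Specificity in percent.
#' @export
specificity_ova <- function(cm, cls, digits = 2) {
  i <- cm_class_index(cm, cls)
  fp <- sum(cm[-i, i])
  tn <- sum(cm[-i, -i])
  if (tn + fp == 0)
    stop("specificity undefined: every sample is truth class ", cls,
         call. = FALSE)
  val <- 100 * tn / (tn + fp)
  if (is.null(digits)) val else round(val, digits)
}

#' Overall accuracy
#'
#' `100 * trace / total`, reported to one decimal by default.
#'
#' @inheritParams sensitivity_ova
#' @param digits decimals to round to; `NULL` for no rounding.
#' @return Accuracy in percent.
#' @export
overall_accuracy <- function(cm, digits = 1) {
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix", call. = FALSE)
  val <- 100 * sum(diag(cm)) / tot
  if (is.null(digits)) val else round(val, digits)
}

#' One-vs-all ROC curve and AUROC
#'
#' Treats the named class as positive and scores each sample by its
#' predicted probability for that class.  Thresholds are the sorted unique
#' scores (equal scores are grouped, so a tie contributes a diagonal
#' segment); the curve runs from (0, 0) to (1, 1) and the AUROC is the
#' trapezoid-rule area, equivalent to the normalized Mann-Whitney U
#' statistic with ties counted half.
#'
#' @param y_true truth labels.
#' @param scores numeric score per sample for class `cls` (e.g. the softmax
#'   probability column), higher = more positive.
#' @param cls the positive class name.
#' @return List with `roc` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auroc`.
#' @export
roc_ova <- function(y_true, scores, cls) {
  y_true <- as_gpr_factor(y_true)
  stopifnot(length(scores) == length(y_true))
  pos <- y_true == cls
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUROC undefined: need both positive and negative samples for ",
         cls, call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- fpr <- numeric(length(thr))
  for (k in seq_along(thr)) {
    call_pos <- scores >= thr[k]
    tpr[k] <- sum(call_pos & pos) / n_pos
    fpr[k] <- sum(call_pos & !pos) / n_neg
  }
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  auroc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  list(roc = roc, auroc = auroc)
}

#' Evaluate a fitted model on a test dataset
#'
#' Computes the confusion matrix, per-class one-vs-all sensitivity and
#' specificity, overall accuracy, and per-class ROC/AUROC from the model's
#' softmax probabilities.
#'
#' @param model a fitted [gpr_lstm()] (or exported model loaded with
#'   [load_exported_model()]).
#' @param ds test [arc_dataset()].
#' @return An `evaluation_report`: `confusion`, `sensitivity`,
#'   `specificity` (named percent vectors), `accuracy`, `roc` (per-class
#'   list from [roc_ova()]), `auroc` (named vector), `macro` (secondary
#'   macro-averages).
#' @export
evaluate_model <- function(model, ds) {
  pr <- predict(model, ds, type = "all")
  report_from_predictions(ds$labels, pr$class, pr$prob)
}

report_from_predictions <- function(y_true, y_pred, prob = NULL) {
  cm <- confusion_matrix3(y_true, y_pred)
  cls_order <- rownames(cm)
  sens <- vapply(cls_order, function(cl) sensitivity_ova(cm, cl), numeric(1))
  spec <- vapply(cls_order, function(cl) specificity_ova(cm, cl), numeric(1))
  roc <- auroc <- NULL
  if (!is.null(prob)) {
    roc <- lapply(stats::setNames(cls_order, cls_order), function(cl)
      roc_ova(y_true, prob[, cl], cl))
    auroc <- vapply(roc, `[[`, numeric(1), "auroc")
  }
  structure(list(
    confusion = cm, sensitivity = sens, specificity = spec,
    accuracy = overall_accuracy(cm), roc = roc, auroc = auroc,
    macro = list(sensitivity = mean(sens), specificity = mean(spec))
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Confusion matrix (rows = truth):\n")
  print(unclass(x$confusion))
  df <- rbind(`Sensitivity (%)` = x$sensitivity,
              `Specificity (%)` = x$specificity)
  if (!is.null(x$auroc)) df <- rbind(df, AUROC = round(x$auroc, 2))
  cat("\n"); print(df)
  cat(sprintf("\nOverall accuracy: %.1f%%\n", x$accuracy))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' JSON summary plus per-class ROC curves as CSV (`fpr`, `tpr`,
#' `threshold`).
#'
#' @param report an `evaluation_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_evaluation_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(confusion = unclass(report$confusion),
         sensitivity = as.list(report$sensitivity),
         specificity = as.list(report$specificity),
         accuracy = report$accuracy,
         auroc = as.list(report$auroc)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(report$roc))
    for (cl in names(report$roc))
      utils::write.csv(report$roc[[cl]]$roc[c("fpr", "tpr", "threshold")],
                       file.path(dir, sprintf("roc_%s.csv", tolower(cl))),
                       row.names = FALSE)
  invisible(dir)
}
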