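#' Classification metrics from a 2x2 confusion matrix
#'
#' Rows are true classes, columns predicted classes. Weighted averages use
#' the true-class support as weights. A class with zero support (or a
#' zero-division in precision) contributes 0 to the corresponding metric
#' and sets the `zero_division` flag.
#'
#' @param cm 2x2 (or k x k) matrix of non-negative counts, total > 0.
#' @return List with `accuracy`, `per_class` (precision/recall/F1 and
#'   support per class), `weighted_precision`, `weighted_recall`,
#'   `weighted_f1` and `zero_division`.
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (any(cm < 0) || sum(cm) <= 0) {
    stop("confusion matrix must hold non-negative counts with total > 0",
         call. = FALSE)
  }
  k <- nrow(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  tp <- diag(cm)
  zero_division <- FALSE
  safe_div <- function(num, den) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0)) zero_division <<- TRUE
    out
  }
  precision <- safe_div(tp, predicted)
  recall <- safe_div(tp, support)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  w <- support / sum(support)
  if (zero_division) {
    warning("zero-support class or empty prediction column; affected metrics set to 0",
            call. = FALSE)
  }
  list(accuracy = sum(tp) / sum(cm),
       per_class = data.frame(class = rownames(cm) %||% as.character(seq_len(k)),
                              precision = unname(precision),
                              recall = unname(recall),
                              f1 = unname(f1),
                              support = unname(support)),
       weighted_precision = sum(w * precision),
       weighted_recall = sum(w * recall),
       weighted_f1 = sum(w * f1),
       zero_division = zero_division)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a classifier on labelled windows
#'
#' Computes the confusion matrix from argmax predictions plus accuracy,
#' weighted precision/recall/F1 and the ROC AUC of the diabetic-class
#' probability (diabetic = positive class). With a single-class test set
#' the AUC is undefined and reported as `NA`.
#'
#' @param object A fitted [ecg_cnn()] or a quantized model
#'   ([quantize_int8()]).
#' @param x Feature matrix.
#' @param y True labels.
#' @return An object of class `ecg_eval`.
#' @export
evaluate_model <- function(object, x, y) {
  if (nrow(x) == 0) stop("empty evaluation set", call. = FALSE)
  y <- as.character(y)
  probs <- predict(object, x, type = "prob")
  classes <- colnames(probs)
  pred <- classes[max.col(probs)]
  cm <- table(factor(y, levels = classes), factor(pred, levels = classes))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("true", "predicted")
  m <- metrics_from_confusion(cm)
  auc <- NA_real_
  if (length(unique(y)) == 2 && "diabetic" %in% classes) {
    roc <- pROC::roc(response = y, predictor = probs[, "diabetic"],
                     levels = c("healthy", "diabetic"), direction = "<",
                     quiet = TRUE)
    auc <- as.numeric(pROC::auc(roc))
  }
  structure(c(list(confusion = cm, auc = auc, n = length(y)), m),
            class = "ecg_eval")
}

#' @export
print.ecg_eval <- function(x, ...) {
  cat("Evaluation on", x$n, "windows\n")
  print(x$confusion)
  cat(sprintf("accuracy %.4f  weighted P %.4f  R %.4f  F1 %.4f  AUC %s\n",
              x$accuracy, x$weighted_precision, x$weighted_recall,
              x$weighted_f1,
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc)))
  invisible(x)
}
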