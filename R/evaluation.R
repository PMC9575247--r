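#' Confusion matrix
#'
#' Entry (i, j) counts samples with true class i predicted as class j
#' (0-based codes, rows = truth).
#'
#' @param truth,pred integer vectors of 0-based class codes, equal length.
#' @param C number of classes.
#' @return C x C integer matrix.
#' @export
confusion_matrix <- function(truth, pred, C) {
  if (length(truth) != length(pred)) {
    stop("truth and pred have different lengths (", length(truth), " vs ",
         length(pred), ")")
  }
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (any(c(truth, pred) < 0L) || any(c(truth, pred) >= C)) {
    stop("labels outside 0..", C - 1L)
  }
  m <- table(factor(truth, levels = 0:(C - 1)),
             factor(pred, levels = 0:(C - 1)))
  matrix(as.integer(m), C, C,
         dimnames = list(true = 0:(C - 1), predicted = 0:(C - 1)))
}

#' Weighted multiclass precision, recall and F1
#'
#' Per-class one-vs-rest precision (`diag_i / colsum_i`) and recall
#' (`diag_i / rowsum_i`) are combined with weights `w_i = rowsum_i / n`,
#' each class's share of the samples. `mode = "standard"` is the usual
#' weighted average `sum(metric_i * w_i)`; `mode = "literal"`
#' additionally divides both weighted sums by the class count L, preserving
#' a printed variant of the formula in which perfect classification scores
#' 1/L (kept for auditability, not as the default). F1 is the harmonic
#' mean `2PR / (P + R)`. A class never predicted gets precision 0 with a
#' warning so the weighted sums stay total.
#'
#' @param confusion C x C confusion matrix (rows = truth).
#' @param mode `"standard"` (default) or `"literal"`.
#' @return list with `precision_w`, `recall_w`, `f1_w` and a `per_class`
#'   data frame (precision, recall, support).
#' @export
weighted_prf <- function(confusion, mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  confusion <- as.matrix(confusion)
  n <- sum(confusion)
  if (n <= 0) stop("confusion matrix is all zeros")
  diagv <- diag(confusion)
  colsum <- colSums(confusion)
  rowsum <- rowSums(confusion)
  if (any(colsum == 0 & rowsum > 0)) {
    warning("class(es) never predicted: precision set to 0 for class ",
            paste(which(colsum == 0 & rowsum > 0) - 1L, collapse = ", "))
  }
  precision_i <- ifelse(colsum > 0, diagv / colsum, 0)
  recall_i <- ifelse(rowsum > 0, diagv / rowsum, 0)
  w <- rowsum / n
  P <- sum(precision_i * w)
  R <- sum(recall_i * w)
  if (mode == "literal") {
    L <- nrow(confusion)
    P <- P / L
    R <- R / L
  }
  f1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  list(precision_w = P, recall_w = R, f1_w = f1,
       per_class = data.frame(precision = precision_i, recall = recall_i,
                              support = w))
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(P0 - Pe) / (1 - Pe)` where `P0` is the
#' observed accuracy (trace / n) and `Pe` the chance agreement
#' `sum(rowsum_i * colsum_i) / n^2` from the marginals.
#'
#' @param confusion C x C confusion matrix.
#' @return kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  n <- sum(confusion)
  if (n <= 0) stop("confusion matrix is all zeros")
  p0 <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (abs(1 - pe) < .Machine$double.eps) {
    stop("kappa undefined: chance agreement Pe = 1 ",
         "(all mass in a single row/column pair)")
  }
  (p0 - pe) / (1 - pe)
}

#' Hamming distance between label vectors
#'
#' For single-label multiclass data: the fraction of samples whose
#' predicted label differs from the truth, in \[0, 1\]; equals
#' `1 - accuracy`.
#'
#' @param truth,pred equal-length nonempty integer vectors.
#' @return scalar in \[0, 1\].
#' @export
hamming_distance <- function(truth, pred) {
  if (length(truth) == 0) stop("empty label vectors")
  if (length(truth) != length(pred)) stop("length mismatch")
  mean(truth != pred)
}

#' Assemble the full evaluation report
#'
#' @param truth,pred integer vectors of 0-based codes.
#' @param C class count; defaults to the largest code + 1.
#' @param labels optional class label strings for the report.
#' @param mode weighted-average mode, see [weighted_prf()].
#' @return an `EvaluationReport`: confusion matrix, accuracy, weighted
#'   precision/recall/F1, Cohen's kappa, Hamming distance, per-class stats.
#' @export
evaluate_predictions <- function(truth, pred, C = max(truth, pred) + 1L,
                                 labels = as.character(0:(C - 1)),
                                 mode = "standard") {
  conf <- confusion_matrix(truth, pred, C)
  prf <- weighted_prf(conf, mode)
  acc <- sum(diag(conf)) / sum(conf)
  structure(list(
    confusion = conf,
    accuracy = acc,
    precision_w = prf$precision_w,
    recall_w = prf$recall_w,
    f1_w = prf$f1_w,
    kappa = cohens_kappa(conf),
    hamming = hamming_distance(truth, pred),
    per_class = list(precision = prf$per_class$precision,
                     recall = prf$per_class$recall,
                     support = prf$per_class$support),
    labels = labels, n = length(truth)), class = "EvaluationReport")
}

#' Evaluate a trained model on a dataset
#'
#' Standardizes with the model's stored parameters when present, predicts
#' by logit argmax (ties to the lowest class index) and assembles the
#' metric report.
#'
#' @param model a trained `dcgn_model`.
#' @param data an `ExpressionDataset` with the model's gene count.
#' @param mode weighted-average mode, see [weighted_prf()].
#' @return an `EvaluationReport`.
#' @export
evaluate_model <- function(model, data, mode = "standard") {
  if (ncol(data$values) != model$n_genes) {
    stop("data has ", ncol(data$values), " genes but model expects ",
         model$n_genes)
  }
  pred <- predict(model, data)
  evaluate_predictions(data$labels, pred, C = model$config$n_classes,
                       labels = model$label_levels %||% data$label_levels,
                       mode = mode)
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat("EvaluationReport on", x$n, "samples,", nrow(x$confusion), "classes\n")
  cat(sprintf("  accuracy  %.4f\n  precision %.4f (weighted)\n", x$accuracy,
              x$precision_w))
  cat(sprintf("  recall    %.4f (weighted)\n  F1        %.4f (weighted)\n",
              x$recall_w, x$f1_w))
  cat(sprintf("  kappa     %.4f\n  hamming   %.4f\n", x$kappa, x$hamming))
  invisible(x)
}
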