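#' Run the full classification pipeline
#'
#' Chains class balancing, splitting, standardization, training and
#' evaluation on a labeled expression dataset:
#' SMOTE (default: applied to the whole dataset before splitting, the
#' published order; `smote_on = "train"` restricts oversampling to the
#' training partition to avoid synthetic-row leakage into the test set),
#' an 80/10/10 stratified split, per-gene standardization (default fitted
#' on the training partition only; `standardize_fit = "all"` fits on the
#' full balanced matrix), network training and test-set evaluation.
#'
#' @param data an `ExpressionDataset`.
#' @param config a [dcgn_config()]; `n_classes` is filled from the data if
#'   it disagrees.
#' @param balance `"smote"` (default), `"undersample"` or `"none"`.
#' @param smote_on `"all"` (published order) or `"train"` (leakage-safe).
#' @param standardize_fit `"train"` (default) or `"all"`.
#' @param undersample_to target per-class size when
#'   `balance = "undersample"`; defaults to the smallest class count.
#' @param verbose print training progress.
#' @return list with `model`, `state`, `report` (test-set
#'   `EvaluationReport`), and the three standardized partitions.
#' @export
run_pipeline <- function(data, config = dcgn_config(),
                         balance = c("smote", "undersample", "none"),
                         smote_on = c("all", "train"),
                         standardize_fit = c("train", "all"),
                         undersample_to = NULL, verbose = FALSE) {
  balance <- match.arg(balance)
  smote_on <- match.arg(smote_on)
  standardize_fit <- match.arg(standardize_fit)
  validate_dataset(data)
  if (config$n_classes != length(data$label_levels)) {
    config$n_classes <- length(data$label_levels)
  }
  if (balance == "smote" && smote_on == "all") {
    data <- smote_oversample(data, k = config$smote_k,
                             threshold = config$smote_threshold,
                             target_count = "majority", seed = config$seed)
  } else if (balance == "undersample") {
    target <- undersample_to %||% min(table(data$labels))
    data <- random_undersample(data, target, seed = config$seed)
  }
  parts <- split_dataset(data, config$split_fractions, seed = config$seed)
  if (balance == "smote" && smote_on == "train") {
    parts$train <- smote_oversample(parts$train, k = config$smote_k,
                                    threshold = config$smote_threshold,
                                    target_count = "majority",
                                    seed = config$seed)
  }
  std <- if (standardize_fit == "train") fit_standardizer(parts$train)
         else fit_standardizer(data)
  parts <- lapply(parts, apply_standardizer, params = std)
  fit <- train_dcgn(parts$train, parts$validation, config, verbose = verbose)
  # evaluate on the pre-standardized partition, then attach the
  # standardizer so later predict() calls can take raw expression values
  report <- evaluate_model(fit$model, parts$test)
  fit$model$standardizer <- std
  list(model = fit$model, state = fit$state, report = report,
       train = parts$train, validation = parts$validation,
       test = parts$test)
}
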