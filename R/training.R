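#' Sparse categorical cross-entropy loss
#'
#' Mean over samples of `-log p[i, y_i]` with `p = softmax(logits)` row by
#' row — the multiclass cross-entropy against integer-coded labels, with
#' the softmax folded in (log-sum-exp form) for numerical stability.
#'
#' @param logits N x C matrix of raw scores.
#' @param labels integer vector of 0-based class codes, length N.
#' @return scalar loss (non-negative).
#' @export
sparse_ce_loss <- function(logits, labels) {
  logits <- as.matrix(logits)
  n <- nrow(logits); C <- ncol(logits)
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels length != number of logit rows")
  if (any(labels < 0L | labels >= C)) {
    stop("label out of range 0..", C - 1L)
  }
  m <- apply(logits, 1, max)
  lse <- m + log(rowSums(exp(logits - m)))
  true_logit <- logits[cbind(seq_len(n), labels + 1L)]
  mean(lse - true_logit)
}

# Softmax probabilities (stable) and the loss gradient wrt logits,
# d/dlogits of sparse_ce_loss = (softmax - onehot) / N.
softmax_rows <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

sparse_ce_grad <- function(logits, labels) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  p[cbind(seq_len(n), as.integer(labels) + 1L)] <-
    p[cbind(seq_len(n), as.integer(labels) + 1L)] - 1
  p / n
}

#' One Adam optimizer step
#'
#' Standard Adam with `beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8` and
#' bias-corrected moment estimates, applied to a named list of weight
#' arrays and a matching list of gradients.
#'
#' @param weights named list of numeric arrays.
#' @param gradients matching named list of gradients.
#' @param moments optimizer state from a previous call, or `NULL` to start
#'   from zero moments.
#' @param lr learning rate.
#' @param t 1-based step counter (used for bias correction).
#' @param beta1,beta2,eps Adam constants.
#' @return list with updated `weights` and `moments`.
#' @export
adam_step <- function(weights, gradients, moments = NULL, lr = 1e-3, t = 1,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(moments)) {
    moments <- list(m = lapply(weights, function(w) array(0, dim(w) %||% length(w))),
                    v = lapply(weights, function(w) array(0, dim(w) %||% length(w))))
  }
  for (nm in names(weights)) {
    gr <- gradients[[nm]]
    if (any(!is.finite(gr))) {
      stop("non-finite gradient in '", nm, "' at step ", t)
    }
    moments$m[[nm]] <- beta1 * moments$m[[nm]] + (1 - beta1) * gr
    moments$v[[nm]] <- beta2 * moments$v[[nm]] + (1 - beta2) * gr^2
    mhat <- moments$m[[nm]] / (1 - beta1^t)
    vhat <- moments$v[[nm]] / (1 - beta2^t)
    upd <- lr * mhat / (sqrt(vhat) + eps)
    w <- weights[[nm]] - as.vector(upd)
    weights[[nm]] <- w
  }
  list(weights = weights, moments = moments)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Loss and full parameter gradients for one batch.
dcgn_loss_and_grads <- function(model, x, labels, training = FALSE) {
  fc <- dcgn_forward_cache(model, x, training = training, keep = TRUE)
  loss <- sparse_ce_loss(fc$logits, labels)
  dlog <- sparse_ce_grad(fc$logits, labels)
  grads <- dcgn_backward(model, fc$cache, dlog)
  list(loss = loss, grads = grads, logits = fc$logits)
}

#' Train a DCGN model
#'
#' Minibatch gradient training (default batch 256, final partial batch
#' kept) minimizing [sparse_ce_loss()] with Adam, shuffling each epoch,
#' early stopping on validation loss with the configured patience, and
#' returning the weights from the best validation epoch. Deterministic for
#' a fixed config/seed/data in R's single-threaded evaluation.
#'
#' @param train,val `ExpressionDataset`s with identical gene sets and label
#'   coding (standardize before calling; see [fit_standardizer()]).
#' @param config a [dcgn_config()] with `n_classes` matching the data.
#' @param verbose print per-epoch progress.
#' @return list with `model` (a `dcgn_model`, weights from the best epoch,
#'   with `label_levels` attached) and `state` (a `TrainState`: history of
#'   epoch, train_loss, val_loss, val_accuracy; `best_epoch`).
#' @export
train_dcgn <- function(train, val, config, verbose = FALSE) {
  validate_dataset(train); validate_dataset(val)
  C <- length(train$label_levels)
  if (C != config$n_classes) {
    stop("data has ", C, " classes but config$n_classes = ",
         config$n_classes)
  }
  model <- build_dcgn(config, ncol(train$values))
  model$label_levels <- train$label_levels
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_accuracy = numeric(0))
  state <- list(epoch = 0L, best_epoch = 0L, history = history)
  if (config$epochs == 0) {
    return(list(model = model, state = structure(state, class = "TrainState")))
  }
  set.seed(config$seed + 1L)
  n <- nrow(train$values)
  best_val <- Inf
  best_params <- model$params
  moments <- NULL
  step_t <- 0L
  wait <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq.int(1L, n, by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      lg <- dcgn_loss_and_grads(model, train$values[idx, , drop = FALSE],
                                train$labels[idx], training = TRUE)
      step_t <- step_t + 1L
      up <- adam_step(model$params, lg$grads, moments,
                      lr = config$learning_rate, t = step_t)
      model$params <- up$weights
      moments <- up$moments
      ep_loss <- ep_loss + lg$loss * length(idx)
    }
    ep_loss <- ep_loss / n
    val_logits <- dcgn_forward(model, val$values, training = FALSE)
    val_loss <- sparse_ce_loss(val_logits, val$labels)
    val_pred <- max.col(val_logits, ties.method = "first") - 1L
    val_acc <- mean(val_pred == val$labels)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss,
                                         val_loss = val_loss,
                                         val_accuracy = val_acc))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f",
                      epoch, ep_loss, val_loss, val_acc))
    }
    if (val_loss < best_val) {
      best_val <- val_loss
      best_params <- model$params
      state$best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stop_patience) break
    }
  }
  model$params <- best_params
  state$epoch <- nrow(history)
  state$history <- history
  list(model = model, state = structure(state, class = "TrainState"))
}

#' Predict class codes for new samples
#'
#' Argmax over the model logits; ties break to the lowest class index.
#'
#' @param object a trained `dcgn_model`.
#' @param newdata numeric matrix (samples x genes) or `ExpressionDataset`.
#'   Must already be standardized the same way as the training data
#'   (or attach `object$standardizer` and it is applied automatically for
#'   `ExpressionDataset` input).
#' @param ... unused.
#' @return integer vector of 0-based predicted class codes.
#' @export
predict.dcgn_model <- function(object, newdata, ...) {
  if (inherits(newdata, "ExpressionDataset")) {
    if (!is.null(object$standardizer)) {
      newdata <- apply_standardizer(newdata, object$standardizer)
    }
    newdata <- newdata$values
  }
  logits <- dcgn_forward(object, newdata, training = FALSE)
  max.col(logits, ties.method = "first") - 1L
}
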