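# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (scalar loops, exhaustive enumeration) so they share
# no code path with the package implementation they check.

# Naive quadruple-loop 2-D cross-correlation with "same" zero padding:
# out spatial size = ceil(in / stride), extra padding on bottom/right.
oracle_conv2d <- function(x, kernels, stride, bias = NULL) {
  d <- dim(x); kd <- dim(kernels)
  out_h <- ceiling(d[2] / stride); out_w <- ceiling(d[3] / stride)
  pad_h <- max((out_h - 1) * stride + kd[1] - d[2], 0)
  pad_w <- max((out_w - 1) * stride + kd[2] - d[3], 0)
  top <- pad_h %/% 2; left <- pad_w %/% 2
  out <- array(0, c(d[1], out_h, out_w, kd[4]))
  for (n in seq_len(d[1])) for (f in seq_len(kd[4])) {
    for (oh in seq_len(out_h)) for (ow in seq_len(out_w)) {
      acc <- 0
      for (i in seq_len(kd[1])) for (j in seq_len(kd[2])) {
        r <- (oh - 1) * stride + i - top
        c <- (ow - 1) * stride + j - left
        if (r >= 1 && r <= d[2] && c >= 1 && c <= d[3]) {
          for (ch in seq_len(d[4])) {
            acc <- acc + x[n, r, c, ch] * kernels[i, j, ch, f]
          }
        }
      }
      out[n, oh, ow, f] <- acc + if (is.null(bias)) 0 else bias[f]
    }
  }
  out
}

# Scalar-loop GRU step: update gate, reset gate, candidate, blend.
oracle_gru_step <- function(x, h, p) {
  H <- p$hidden_size; Fw <- length(x)
  conc <- c(h, x)
  z <- r <- hc <- hnew <- numeric(H)
  for (j in seq_len(H)) {
    az <- p$b_z[j]; ar <- p$b_r[j]
    for (i in seq_along(conc)) {
      az <- az + conc[i] * p$W_z[i, j]
      ar <- ar + conc[i] * p$W_r[i, j]
    }
    z[j] <- 1 / (1 + exp(-az))
    r[j] <- 1 / (1 + exp(-ar))
  }
  conc_c <- c(h * r, x)
  for (j in seq_len(H)) {
    ac <- p$b[j]
    for (i in seq_along(conc_c)) ac <- ac + conc_c[i] * p$W[i, j]
    hc[j] <- tanh(ac)
    hnew[j] <- (1 - z[j]) * hc[j] + z[j] * h[j]
  }
  hnew
}

# Per-class precision/recall from raw label vectors (one-vs-rest counts),
# combined by class share of the truth vector.
oracle_weighted_prf <- function(truth, pred, C) {
  n <- length(truth)
  P <- R <- 0
  for (cls in 0:(C - 1)) {
    tp <- sum(truth == cls & pred == cls)
    fp <- sum(truth != cls & pred == cls)
    fn <- sum(truth == cls & pred != cls)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    w <- sum(truth == cls) / n
    P <- P + prec * w
    R <- R + rec * w
  }
  f1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  c(precision = P, recall = R, f1 = f1)
}

oracle_kappa <- function(truth, pred, C) {
  n <- length(truth)
  p0 <- sum(truth == pred) / n
  pe <- 0
  for (cls in 0:(C - 1)) {
    pe <- pe + sum(truth == cls) * sum(pred == cls)
  }
  pe <- pe / n^2
  (p0 - pe) / (1 - pe)
}

# Exhaustive k nearest same-class neighbours by scanning every pair.
oracle_knn <- function(x, k) {
  n <- nrow(x)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- rep(Inf, n)
    for (j in seq_len(n)) {
      if (i != j) d[j] <- sqrt(sum((x[i, ] - x[j, ])^2))
    }
    out[i, ] <- order(d)[seq_len(k)]
  }
  out
}

# Nearest-centroid classifier for the separability check.
oracle_nearest_centroid <- function(train_x, train_y, test_x) {
  classes <- sort(unique(train_y))
  centroids <- t(vapply(classes, function(cls) {
    colMeans(train_x[train_y == cls, , drop = FALSE])
  }, numeric(ncol(train_x))))
  apply(test_x, 1, function(row) {
    classes[which.min(colSums((t(centroids) - row)^2))]
  })
}

# Small helper configs/datasets reused across files.
tiny_net_config <- function(...) {
  dcgn_config(fc_nodes = 16L, conv1_kernels = 4L, conv2_kernels = 3L,
              gru_units = 3L, classifier_nodes = c(8L, 6L, 4L),
              n_classes = 3L, dropout_rates = c(0, 0), batch_size = 32L,
              epochs = 5L, seed = 7L, ...)
}

make_labeled_dataset <- function(counts, n_genes = 5, seed = 1,
                                 sep = 0) {
  set.seed(seed)
  labels <- rep(seq_along(counts) - 1L, counts)
  x <- matrix(rnorm(length(labels) * n_genes), length(labels))
  if (sep != 0) x <- x + sep * labels
  expression_dataset(x, labels = labels,
                     label_levels = LETTERS[seq_along(counts)])
}
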