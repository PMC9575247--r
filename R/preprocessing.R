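#' Identify minority classes
#'
#' A class is a minority when its sample count is strictly below
#' `threshold` times the total sample size (default 15%), the rule used to
#' decide which classes SMOTE resamples.
#'
#' @param labels integer vector of 0-based class codes.
#' @param threshold fraction of the total below which a class is minority.
#' @return integer vector of minority class codes (possibly empty).
#' @export
identify_minority_classes <- function(labels, threshold = 0.15) {
  if (length(labels) == 0) stop("empty label vector")
  stopifnot(threshold > 0, threshold < 1)
  counts <- table(labels)
  cutoff <- threshold * length(labels)
  as.integer(names(counts)[counts < cutoff])
}

#' SMOTE minority oversampling
#'
#' For each minority class (count below `threshold` of the total), new rows
#' are synthesized by linear interpolation
#' `x_new = x_i + (x_n - x_i) * r`, `r ~ Uniform(0,1)`, where `x_n` is
#' drawn uniformly from the `k` nearest same-class neighbours of a random
#' class member `x_i` under Euclidean distance, until the class reaches
#' `target_count`. Original rows are never altered; synthetic rows carry
#' their seed class label and are flagged in `synthetic_mask`.
#'
#' @param data an `ExpressionDataset`.
#' @param k neighbourhood size; clamped to (class size - 1) with a warning.
#' @param threshold minority-class fraction cutoff (strict `<`).
#' @param target_count per-minority-class post-sampling size: an integer or
#'   `"majority"` (the largest class count, the default).
#' @param seed RNG seed for reproducibility.
#' @return the augmented `ExpressionDataset`.
#' @export
smote_oversample <- function(data, k = 5, threshold = 0.15,
                             target_count = "majority", seed = 1L) {
  validate_dataset(data)
  if (k <= 0) stop("k must be a positive integer")
  labels <- data$labels
  counts <- table(labels)
  minority <- identify_minority_classes(labels, threshold)
  if (identical(target_count, "majority")) {
    target_count <- max(counts)
  }
  target_count <- as.integer(target_count)
  set.seed(seed)
  new_rows <- list()
  new_labels <- integer(0)
  for (cls in minority) {
    idx <- which(labels == cls)
    n_c <- length(idx)
    n_new <- target_count - n_c
    if (n_new <= 0) next
    if (n_c < 2) {
      stop("minority class ", data$label_levels[cls + 1],
           " has a single member; SMOTE needs at least 2")
    }
    k_c <- k
    if (k_c >= n_c) {
      k_c <- n_c - 1L
      warning("k clamped to ", k_c, " for class ",
              data$label_levels[cls + 1], " (size ", n_c, ")")
    }
    nn <- knn_same_class(data$values[idx, , drop = FALSE], k_c)
    i_seed <- sample.int(n_c, n_new, replace = TRUE)
    j_nb <- sample.int(k_c, n_new, replace = TRUE)
    r <- stats::runif(n_new)
    xi <- data$values[idx[i_seed], , drop = FALSE]
    xn <- data$values[idx[nn[cbind(i_seed, j_nb)]], , drop = FALSE]
    new_rows[[length(new_rows) + 1]] <- xi + (xn - xi) * r
    new_labels <- c(new_labels, rep(cls, n_new))
  }
  if (length(new_rows) == 0) return(data)
  synth <- do.call(rbind, new_rows)
  synth_ids <- paste0("synth_", data$label_levels[new_labels + 1], "_",
                      stats::ave(new_labels, new_labels, FUN = seq_along))
  expression_dataset(
    rbind(data$values, synth),
    labels = c(data$labels, new_labels),
    sample_ids = c(data$sample_ids, synth_ids),
    gene_ids = data$gene_ids,
    label_levels = data$label_levels,
    synthetic_mask = c(data$synthetic_mask, rep(TRUE, nrow(synth))))
}

# k nearest neighbours within a class: row i of the result holds the k
# nearest other rows of x (Euclidean), ties broken by original row index.
knn_same_class <- function(x, k) {
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  res <- apply(d, 1, function(row) order(row)[seq_len(k)])
  if (k == 1) matrix(res, ncol = 1) else t(res)
}

#' Random undersampling to a fixed per-class size
#'
#' The classical alternative to SMOTE: every class is reduced to
#' `target_count` rows by uniform sampling without replacement.
#'
#' @param data an `ExpressionDataset`.
#' @param target_count rows to keep per class; must not exceed any class
#'   count.
#' @param seed RNG seed.
#' @return the reduced `ExpressionDataset` (original row order preserved).
#' @export
random_undersample <- function(data, target_count, seed = 1L) {
  validate_dataset(data)
  counts <- table(data$labels)
  too_small <- names(counts)[counts < target_count]
  if (length(too_small) > 0) {
    stop("target_count ", target_count, " exceeds the size of class(es): ",
         paste(data$label_levels[as.integer(too_small) + 1], collapse = ", "))
  }
  set.seed(seed)
  keep <- unlist(lapply(sort(unique(data$labels)), function(cls) {
    idx <- which(data$labels == cls)
    sort(sample(idx, target_count))
  }))
  subset_dataset(data, sort(keep))
}

#' Fit per-gene standardization parameters
#'
#' Column means and population standard deviations (divide by n, not
#' n - 1), fitted once and reapplied to any partition via
#' [apply_standardizer()].
#'
#' @param data an `ExpressionDataset` with at least 2 samples.
#' @return a `StandardizationParams` list with `mean` and `std` vectors.
#' @export
fit_standardizer <- function(data) {
  validate_dataset(data)
  n <- nrow(data$values)
  if (n < 2) stop("need at least 2 samples to fit a standardizer")
  mu <- colMeans(data$values)
  sigma <- sqrt(colMeans(sweep(data$values, 2, mu)^2))
  structure(list(mean = mu, std = sigma, gene_ids = data$gene_ids),
            class = "StandardizationParams")
}

#' Apply fitted standardization parameters
#'
#' Each column becomes `(x - mean) / std`. Zero-variance columns map to
#' all-zeros rather than dividing by zero: a constant gene carries no
#' information and must not crash the pipeline.
#'
#' @param data an `ExpressionDataset`.
#' @param params a `StandardizationParams` from [fit_standardizer()].
#' @return the standardized `ExpressionDataset`.
#' @export
apply_standardizer <- function(data, params) {
  stopifnot(inherits(params, "StandardizationParams"))
  if (length(params$mean) != ncol(data$values)) {
    stop("standardizer fitted on ", length(params$mean),
         " genes but data has ", ncol(data$values))
  }
  std <- params$std
  safe <- ifelse(std == 0, 1, std)
  v <- sweep(sweep(data$values, 2, params$mean), 2, safe, "/")
  if (any(std == 0)) v[, std == 0] <- 0
  out <- data
  out$values <- v
  out
}

#' Serialize standardization parameters to JSON
#' @param params a `StandardizationParams`.
#' @param path output path.
#' @export
write_standardizer <- function(params, path) {
  jsonlite::write_json(unclass(params), path, digits = NA)
  invisible(NULL)
}

#' Read standardization parameters from JSON
#' @param path JSON path written by [write_standardizer()].
#' @return a `StandardizationParams`.
#' @export
read_standardizer <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = x$mean, std = x$std, gene_ids = x$gene_ids),
            class = "StandardizationParams")
}

#' Split a dataset into train / validation / test partitions
#'
#' Deterministic under `seed`. Sizes follow floor-floor-remainder: the
#' train and validation counts are floored, the test partition takes the
#' remainder (4221 samples at 0.8/0.1/0.1 gives 3376/422/423). With
#' `stratified = TRUE` the rule is applied within each class, preserving
#' class proportions to rounding.
#'
#' @param data an `ExpressionDataset`.
#' @param fractions length-3 numeric summing to 1; default `c(.8,.1,.1)`.
#' @param seed RNG seed.
#' @param stratified preserve per-class proportions (default `TRUE`).
#' @return named list `train`, `validation`, `test` of `ExpressionDataset`s.
#' @export
split_dataset <- function(data, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                          stratified = TRUE) {
  validate_dataset(data)
  stopifnot(length(fractions) == 3)
  if (abs(sum(fractions) - 1) > 1e-8) stop("split fractions must sum to 1")
  set.seed(seed)
  assign_block <- function(idx) {
    n <- length(idx)
    n_tr <- floor(fractions[1] * n)
    n_va <- floor(fractions[2] * n)
    idx <- sample(idx)
    list(train = idx[seq_len(n_tr)],
         validation = idx[n_tr + seq_len(n_va)],
         test = idx[setdiff(seq_len(n), seq_len(n_tr + n_va))])
  }
  if (stratified) {
    parts <- lapply(sort(unique(data$labels)),
                    function(cls) assign_block(which(data$labels == cls)))
    out <- list(train = sort(unlist(lapply(parts, `[[`, "train"))),
                validation = sort(unlist(lapply(parts, `[[`, "validation"))),
                test = sort(unlist(lapply(parts, `[[`, "test"))))
  } else {
    out <- assign_block(seq_len(nrow(data$values)))
  }
  sizes <- vapply(out, length, integer(1))
  if (any(sizes == 0)) {
    stop("empty partition(s): ",
         paste(names(sizes)[sizes == 0], collapse = ", "))
  }
  lapply(out, function(idx) subset_dataset(data, idx))
}
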