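#' Expression dataset container
#'
#' The universal currency of the pipeline: a samples x genes numeric matrix
#' with per-sample integer class labels. Labels are stored as a 0-based
#' integer code (`0 .. C-1`); the original label strings are kept in
#' `label_levels` so the coding is invertible. Rows synthesized by SMOTE are
#' flagged in `synthetic_mask`.
#'
#' @param values numeric matrix, samples in rows, genes in columns.
#' @param labels integer vector of 0-based class codes, or a character/factor
#'   vector of raw labels (then recoded via lexicographic order).
#' @param sample_ids,gene_ids optional character vectors; default to the
#'   dimnames of `values` or generated ids.
#' @param label_levels character vector mapping code `i` to the original
#'   label string `label_levels[i + 1]`. Required when `labels` is already
#'   an integer code; derived otherwise.
#' @param synthetic_mask logical vector, `TRUE` for SMOTE-generated rows.
#'
#' @return An object of class `ExpressionDataset`: a list with fields
#'   `values`, `labels`, `label_levels`, `sample_ids`, `gene_ids`,
#'   `synthetic_mask`.
#' @export
expression_dataset <- function(values, labels, sample_ids = NULL,
                               gene_ids = NULL, label_levels = NULL,
                               synthetic_mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(n))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(values)))
  }
  if (is.character(labels) || is.factor(labels)) {
    raw <- as.character(labels)
    if (is.null(label_levels)) label_levels <- sort(unique(raw))
    labels <- match(raw, label_levels) - 1L
    if (anyNA(labels)) {
      stop("labels contain values outside label_levels: ",
           paste(unique(raw[is.na(labels)]), collapse = ", "))
    }
  } else {
    labels <- as.integer(labels)
    if (is.null(label_levels)) {
      label_levels <- as.character(sort(unique(labels)))
      labels <- match(labels, sort(unique(labels))) - 1L
    }
  }
  if (is.null(synthetic_mask)) synthetic_mask <- rep(FALSE, n)
  obj <- structure(
    list(values = values, labels = labels, label_levels = label_levels,
         sample_ids = as.character(sample_ids),
         gene_ids = as.character(gene_ids),
         synthetic_mask = as.logical(synthetic_mask)),
    class = "ExpressionDataset")
  validate_dataset(obj)
  obj
}

validate_dataset <- function(x) {
  stopifnot(inherits(x, "ExpressionDataset"))
  n <- nrow(x$values)
  if (length(x$sample_ids) != n) {
    stop("sample_ids length (", length(x$sample_ids),
         ") != number of rows (", n, ")")
  }
  if (anyDuplicated(x$sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(x$sample_ids[duplicated(x$sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(x$gene_ids)) stop("duplicate gene ids")
  if (length(x$gene_ids) != ncol(x$values)) {
    stop("gene_ids length != number of columns")
  }
  if (length(x$labels) != n) stop("labels length != number of rows")
  if (length(x$synthetic_mask) != n) stop("synthetic_mask length != rows")
  if (anyNA(x$values)) stop("expression matrix contains missing values")
  C <- length(x$label_levels)
  if (n > 0) {
    if (C < 2) stop("need at least 2 classes, found ", C)
    if (any(x$labels < 0L | x$labels >= C)) {
      stop("labels outside 0..", C - 1L)
    }
  }
  invisible(x)
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", nrow(x$values), "samples x",
      ncol(x$values), "genes\n")
  cat("classes (", length(x$label_levels), "): ",
      paste(x$label_levels, collapse = ", "), "\n", sep = "")
  tab <- table(factor(x$labels, levels = seq_along(x$label_levels) - 1L))
  cat("class counts:", paste(as.integer(tab), collapse = ", "), "\n")
  if (any(x$synthetic_mask)) {
    cat(sum(x$synthetic_mask), "SMOTE-synthetic rows\n")
  }
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

#' Number of classes in a dataset
#' @param data an `ExpressionDataset`.
#' @return integer class count C.
#' @export
n_classes <- function(data) length(data$label_levels)

#' Subset a dataset by row indices
#' @param data an `ExpressionDataset`.
#' @param idx integer row indices to keep.
#' @return the subsetted `ExpressionDataset` (class coding unchanged).
#' @export
subset_dataset <- function(data, idx) {
  expression_dataset(data$values[idx, , drop = FALSE],
                     labels = data$labels[idx],
                     sample_ids = data$sample_ids[idx],
                     gene_ids = data$gene_ids,
                     label_levels = data$label_levels,
                     synthetic_mask = data$synthetic_mask[idx])
}

#' Decode 0-based class codes back to original label strings
#' @param data an `ExpressionDataset`.
#' @param codes integer codes; defaults to the dataset's own labels.
#' @return character vector of original labels.
#' @export
decode_labels <- function(data, codes = data$labels) {
  data$label_levels[codes + 1L]
}
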