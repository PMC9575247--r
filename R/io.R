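#' Load an expression matrix and label file
#'
#' The matrix file is CSV or TSV with sample ids in the first column and a
#' header row of gene ids. The labels file maps sample id to class label
#' (columns `sample_id,label`, header optional in that order). Labels are
#' re-coded to contiguous 0..C-1 by lexicographic order of the original
#' label strings; the mapping is preserved in the returned object.
#'
#' @param matrix_path path to the expression matrix (samples x genes).
#' @param labels_path path to the two-column label file.
#' @param sep field delimiter; `NULL` (default) sniffs `,` vs tab from the
#'   first line.
#' @param transpose set `TRUE` for gene-major files (genes in rows).
#' @param impute_missing if `TRUE`, missing cells are replaced by the
#'   per-gene mean; default rejects missing values.
#' @return an [expression_dataset()].
#' @export
load_expression <- function(matrix_path, labels_path, sep = NULL,
                            transpose = FALSE, impute_missing = FALSE) {
  sep_m <- if (is.null(sep)) sniff_sep(matrix_path) else sep
  df <- utils::read.table(matrix_path, header = TRUE, sep = sep_m,
                          row.names = 1, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))
    # locate the first offending cell for a coordinate-bearing message
    for (j in bad) {
      v <- suppressWarnings(as.numeric(df[[j]]))
      i <- which(is.na(v) & !is.na(df[[j]]))[1]
      if (!is.na(i)) {
        stop("non-numeric value '", df[[j]][i], "' at row '", rownames(df)[i],
             "', column '", colnames(df)[j], "'")
      }
    }
    stop("non-numeric columns in expression matrix: ",
         paste(colnames(df)[bad], collapse = ", "))
  }
  if (transpose) m <- t(m)
  if (anyNA(m)) {
    if (!impute_missing) {
      idx <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop("missing value at row '", rownames(m)[idx[1]], "', column '",
           colnames(m)[idx[2]], "' (use impute_missing = TRUE to impute)")
    }
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- mean(m[!nas, j])
    }
  }
  sep_l <- if (is.null(sep)) sniff_sep(labels_path) else sep
  lab <- utils::read.table(labels_path, header = has_label_header(labels_path, sep_l),
                           sep = sep_l, stringsAsFactors = FALSE,
                           comment.char = "")
  if (ncol(lab) < 2) stop("labels file needs two columns: sample_id, label")
  lab_ids <- as.character(lab[[1]])
  missing_ids <- setdiff(rownames(m), lab_ids)
  if (length(missing_ids) > 0) {
    stop("sample ids missing from labels file: ",
         paste(missing_ids, collapse = ", "))
  }
  ord <- match(rownames(m), lab_ids)
  expression_dataset(m, labels = as.character(lab[[2]])[ord],
                     sample_ids = rownames(m), gene_ids = colnames(m))
}

sniff_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

has_label_header <- function(path, sep) {
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  length(first) >= 2 &&
    tolower(first[1]) %in% c("sample_id", "sample", "id")
}

#' Write an expression dataset to matrix + label files
#'
#' Inverse of [load_expression()]: writes the samples x genes matrix with a
#' header of gene ids and a first column of sample ids, plus a two-column
#' label file carrying the original (decoded) label strings.
#'
#' @param data an `ExpressionDataset`.
#' @param matrix_path,labels_path output paths.
#' @param sep delimiter, default `,`.
#' @export
write_expression <- function(data, matrix_path, labels_path, sep = ",") {
  df <- data.frame(sample_id = data$sample_ids,
                   data$values, check.names = FALSE)
  colnames(df) <- c("sample_id", data$gene_ids)
  utils::write.table(df, matrix_path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  lab <- data.frame(sample_id = data$sample_ids,
                    label = decode_labels(data))
  utils::write.table(lab, labels_path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(NULL)
}

#' Write an evaluation report to JSON
#'
#' Serializes the confusion matrix, the five scalar metrics and the
#' per-class breakdown; [read_report()] round-trips the file losslessly.
#'
#' @param report an `EvaluationReport` from [evaluate_predictions()].
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "EvaluationReport"))
  scalars <- c(report$accuracy, report$precision_w, report$recall_w,
               report$f1_w, report$kappa, report$hamming)
  if (any(!is.finite(scalars))) stop("report contains non-finite metrics")
  out <- list(
    labels = report$labels,
    confusion = unname(apply(report$confusion, 1, as.integer,
                             simplify = FALSE)),
    accuracy = report$accuracy,
    precision_weighted = report$precision_w,
    recall_weighted = report$recall_w,
    f1_weighted = report$f1_w,
    kappa = report$kappa,
    hamming = report$hamming,
    per_class = list(precision = unname(report$per_class$precision),
                     recall = unname(report$per_class$recall),
                     support = unname(report$per_class$support)),
    n = report$n
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(NULL)
}

#' Read an evaluation report written by [write_report()]
#' @param path JSON path.
#' @return the reconstructed `EvaluationReport`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  conf <- x$confusion
  if (is.list(conf)) conf <- do.call(rbind, conf)
  conf <- matrix(as.integer(conf), nrow = length(x$labels), byrow = FALSE,
                 dimnames = list(true = x$labels, predicted = x$labels))
  structure(list(
    confusion = conf,
    accuracy = x$accuracy, precision_w = x$precision_weighted,
    recall_w = x$recall_weighted, f1_w = x$f1_weighted,
    kappa = x$kappa, hamming = x$hamming,
    per_class = list(precision = x$per_class$precision,
                     recall = x$per_class$recall,
                     support = x$per_class$support),
    labels = x$labels, n = x$n), class = "EvaluationReport")
}

#' Read a JSON network/training configuration
#'
#' Fields use the exact names of [dcgn_config()]; absent fields fall back
#' to the defaults.
#' @param path JSON path.
#' @return a `DCGNConfig`.
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(dcgn_config, x)
}

#' Write a configuration to JSON
#' @param config a `DCGNConfig`.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "DCGNConfig"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(NULL)
}
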