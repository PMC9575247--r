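#' Network and training configuration
#'
#' Collects every architecture and training hyperparameter. Defaults are
#' the published operating point: feature-learning widths 1024 / 128 / 64 /
#' 64 (FC nodes, conv-1 kernels, conv-2 kernels, GRU units per direction),
#' classifier widths 128 / 64 / 32 / `n_classes`, batch size 256, Adam with
#' learning rate 1e-3, dropout rates 0.6 and 0.7.
#'
#' @param fc_nodes width of the first fully connected layer; must be a
#'   perfect square so the output reshapes to a square single-channel map.
#' @param conv1_kernels,conv2_kernels kernel counts of the two conv layers.
#' @param kernel_size conv kernel spatial size, length-2 integer.
#' @param conv_strides stride of both conv layers.
#' @param pool_size max-pool window (stride equal to the window).
#' @param gru_units GRU hidden size per direction.
#' @param classifier_nodes widths of the three hidden classifier layers.
#' @param n_classes number of output classes C.
#' @param dropout_rates length-2: rate after classifier layers 1-2, and
#'   after layer 3.
#' @param batch_size minibatch size (final partial batch kept).
#' @param learning_rate Adam step size.
#' @param epochs maximum training epochs.
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping; `Inf` disables early stopping.
#' @param seed RNG seed for init, shuffling and dropout.
#' @param activation one of `"gelu_approx"` (default), `"gelu_exact"`,
#'   `"relu"`, `"elu"`, `"tanh"`.
#' @param smote_threshold minority-class fraction cutoff.
#' @param smote_k SMOTE neighbourhood size.
#' @param split_fractions train/validation/test fractions.
#' @param bigru_axis `"rows"` (default) feeds the pooled map to the BiGRU
#'   row-by-row (time = height, features = width x channels);
#'   `"columns"` transposes first.
#' @return a validated `DCGNConfig` list.
#' @export
dcgn_config <- function(fc_nodes = 1024L, conv1_kernels = 128L,
                        conv2_kernels = 64L, kernel_size = c(3L, 3L),
                        conv_strides = 2L, pool_size = c(2L, 2L),
                        gru_units = 64L, classifier_nodes = c(128L, 64L, 32L),
                        n_classes = 2L, dropout_rates = c(0.6, 0.7),
                        batch_size = 256L, learning_rate = 1e-3,
                        epochs = 100L, early_stop_patience = 10L,
                        seed = 1L, activation = "gelu_approx",
                        smote_threshold = 0.15, smote_k = 5L,
                        split_fractions = c(0.8, 0.1, 0.1),
                        bigru_axis = "rows") {
  cfg <- list(fc_nodes = as.integer(fc_nodes),
              conv1_kernels = as.integer(conv1_kernels),
              conv2_kernels = as.integer(conv2_kernels),
              kernel_size = as.integer(kernel_size),
              conv_strides = as.integer(conv_strides),
              pool_size = as.integer(pool_size),
              gru_units = as.integer(gru_units),
              classifier_nodes = as.integer(classifier_nodes),
              n_classes = as.integer(n_classes),
              dropout_rates = as.numeric(dropout_rates),
              batch_size = as.integer(batch_size),
              learning_rate = as.numeric(learning_rate),
              epochs = as.integer(epochs),
              early_stop_patience = as.numeric(early_stop_patience),
              seed = as.integer(seed),
              activation = as.character(activation),
              smote_threshold = as.numeric(smote_threshold),
              smote_k = as.integer(smote_k),
              split_fractions = as.numeric(split_fractions),
              bigru_axis = as.character(bigru_axis))
  class(cfg) <- "DCGNConfig"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  side <- sqrt(cfg$fc_nodes)
  if (side != floor(side)) {
    stop("fc_nodes = ", cfg$fc_nodes, " is not a perfect square; ",
         "the FC output must reshape to a square map")
  }
  if (abs(sum(cfg$split_fractions) - 1) > 1e-8) {
    stop("split_fractions must sum to 1")
  }
  if (any(cfg$dropout_rates < 0 | cfg$dropout_rates >= 1)) {
    stop("dropout rates must lie in [0, 1)")
  }
  if (length(cfg$dropout_rates) != 2) stop("dropout_rates must have length 2")
  if (!cfg$activation %in% activation_kinds()) {
    stop("unknown activation '", cfg$activation, "'")
  }
  if (!cfg$bigru_axis %in% c("rows", "columns")) {
    stop("bigru_axis must be 'rows' or 'columns'")
  }
  if (cfg$n_classes < 2) stop("n_classes must be at least 2")
  if (length(cfg$classifier_nodes) != 3) {
    stop("classifier_nodes must list the three hidden widths")
  }
  if (cfg$smote_k < 1) stop("smote_k must be >= 1")
  if (cfg$learning_rate <= 0 || cfg$batch_size < 1 || cfg$epochs < 0) {
    stop("invalid training hyperparameters")
  }
  invisible(cfg)
}

#' @export
print.DCGNConfig <- function(x, ...) {
  side <- as.integer(sqrt(x$fc_nodes))
  cat("DCGNConfig\n")
  cat("  feature learning: fc", x$fc_nodes, "-> map", side, "x", side,
      "| conv1", x$conv1_kernels, "| conv2", x$conv2_kernels,
      "| gru", x$gru_units, "per direction\n")
  cat("  classifier:", paste(x$classifier_nodes, collapse = " / "),
      "->", x$n_classes, "classes, dropout",
      paste(x$dropout_rates, collapse = "/"), "\n")
  cat("  training: batch", x$batch_size, ", lr", x$learning_rate,
      ", epochs", x$epochs, ", patience", x$early_stop_patience,
      ", activation", x$activation, ", seed", x$seed, "\n")
  invisible(x)
}
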