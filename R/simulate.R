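#' Specification for a synthetic expression dataset
#'
#' Describes a Gaussian-mixture, class-structured expression matrix:
#' each class shifts the means of its own disjoint block of informative
#' genes by `effect_size` (in units of `noise_sd`); all other genes are
#' pure noise. An optional equicorrelation can be induced among a sample's
#' informative genes, and a log-normal option produces positive
#' RNA-seq-like values.
#'
#' @param n_classes number of classes C (>= 2).
#' @param class_counts integer vector of per-class sample counts (each
#'   >= 2 so SMOTE has neighbours).
#' @param n_genes total gene count.
#' @param n_informative number of class-informative genes, split evenly
#'   (disjointly) across classes.
#' @param effect_size mean shift of a class's informative genes, in units
#'   of `noise_sd`.
#' @param noise_sd residual standard deviation.
#' @param within_class_corr equicorrelation in \[0, 1) among a sample's
#'   informative genes.
#' @param log_normal exponentiate values for RNA-seq-like positivity.
#' @param seed RNG seed.
#' @return a validated `SimulationSpec` list.
#' @export
simulation_spec <- function(n_classes = 3L, class_counts = c(40L, 40L, 40L),
                            n_genes = 256L, n_informative = 30L,
                            effect_size = 3, noise_sd = 1,
                            within_class_corr = 0, log_normal = FALSE,
                            seed = 1L) {
  spec <- list(n_classes = as.integer(n_classes),
               class_counts = as.integer(class_counts),
               n_genes = as.integer(n_genes),
               n_informative = as.integer(n_informative),
               effect_size = as.numeric(effect_size),
               noise_sd = as.numeric(noise_sd),
               within_class_corr = as.numeric(within_class_corr),
               log_normal = isTRUE(log_normal),
               seed = as.integer(seed))
  problems <- character(0)
  if (spec$n_classes < 2) problems <- c(problems, "n_classes must be >= 2")
  if (length(spec$class_counts) != spec$n_classes) {
    problems <- c(problems, "class_counts length must equal n_classes")
  }
  if (any(spec$class_counts < 2)) {
    problems <- c(problems, "every class needs >= 2 samples")
  }
  if (spec$n_informative > spec$n_genes) {
    problems <- c(problems, "n_informative exceeds n_genes")
  }
  if (spec$effect_size < 0) problems <- c(problems, "effect_size must be >= 0")
  if (spec$noise_sd <= 0) problems <- c(problems, "noise_sd must be > 0")
  if (spec$within_class_corr < 0 || spec$within_class_corr >= 1) {
    problems <- c(problems, "within_class_corr must be in [0, 1)")
  }
  if (length(problems) > 0) {
    stop("invalid simulation spec: ", paste(problems, collapse = "; "))
  }
  structure(spec, class = "SimulationSpec")
}

#' Simulate a class-structured expression dataset
#'
#' Draws samples from the Gaussian mixture described by a
#' [simulation_spec()]: class c gets mean `effect_size * noise_sd` on its
#' own informative-gene block and 0 elsewhere. The ground truth (per-class
#' informative genes and mean vectors) is attached as the `ground_truth`
#' attribute for test assertions.
#'
#' @param spec a `SimulationSpec`.
#' @return an [expression_dataset()] with classes `class_1 .. class_C` and
#'   attribute `ground_truth` (list of `informative_genes` and
#'   `class_means`).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  C <- spec$n_classes
  n <- sum(spec$class_counts)
  G <- spec$n_genes
  per <- spec$n_informative %/% C
  info <- vector("list", C)
  for (c in seq_len(C)) {
    info[[c]] <- if (per > 0) ((c - 1) * per + 1):(c * per) else integer(0)
  }
  mu <- matrix(0, C, G)
  for (c in seq_len(C)) {
    mu[c, info[[c]]] <- spec$effect_size * spec$noise_sd
  }
  labels <- rep(seq_len(C) - 1L, spec$class_counts)
  x <- matrix(stats::rnorm(n * G, sd = spec$noise_sd), n, G)
  if (spec$within_class_corr > 0 && spec$n_informative > 0) {
    rho <- spec$within_class_corr
    inf_all <- seq_len(per * C)
    shared <- stats::rnorm(n, sd = spec$noise_sd)
    x[, inf_all] <- sqrt(rho) * shared +
      sqrt(1 - rho) * x[, inf_all, drop = FALSE]
  }
  x <- x + mu[labels + 1L, , drop = FALSE]
  if (spec$log_normal) x <- exp(x)
  ds <- expression_dataset(
    x, labels = labels,
    sample_ids = sprintf("s%04d", seq_len(n)),
    gene_ids = sprintf("g%05d", seq_len(G)),
    label_levels = paste0("class_", seq_len(C)))
  attr(ds, "ground_truth") <- list(
    informative_genes = lapply(info, function(i) sprintf("g%05d", i)),
    class_means = mu)
  ds
}

#' Named simulation presets
#'
#' `"tiny"`: 3 balanced classes x 40 samples, 256 genes — fast enough for
#' a test suite. `"brca_like"`: 6 classes, 20,000 genes and the severe
#' imbalance of a breast-cancer subtype cohort (class counts 330, 239,
#' 721, 491, 202, 150; three classes fall under the 15% minority cutoff).
#' `"blca_like"`: bladder-cancer-like; `system` picks the labeling scheme —
#' `"mda"` (3 classes, 1010 samples), `"tcga"` (5, 761), `"cit_curie"`
#' (7, 909) or `"lund"` (10, 1185) — with mildly imbalanced counts.
#'
#' @param name preset name.
#' @param system labeling system for `"blca_like"`.
#' @param seed RNG seed stored in the spec.
#' @return a `SimulationSpec`.
#' @export
preset <- function(name = c("tiny", "brca_like", "blca_like"),
                   system = c("mda", "tcga", "cit_curie", "lund"),
                   seed = 1L) {
  name <- match.arg(name)
  switch(name,
    tiny = simulation_spec(n_classes = 3L, class_counts = rep(40L, 3),
                           n_genes = 256L, n_informative = 30L,
                           effect_size = 3, noise_sd = 1, seed = seed),
    brca_like = simulation_spec(
      n_classes = 6L,
      class_counts = c(330L, 239L, 721L, 491L, 202L, 150L),
      n_genes = 20000L, n_informative = 300L,
      effect_size = 2, noise_sd = 1, seed = seed),
    blca_like = {
      system <- match.arg(system)
      cls <- switch(system, mda = 3L, tcga = 5L, cit_curie = 7L, lund = 10L)
      total <- switch(system, mda = 1010L, tcga = 761L, cit_curie = 909L,
                      lund = 1185L)
      # geometric-ish decay so later subtypes are progressively rarer
      w <- 0.75^(seq_len(cls) - 1)
      counts <- pmax(2L, as.integer(round(total * w / sum(w))))
      counts[1] <- counts[1] + (total - sum(counts))
      simulation_spec(n_classes = cls, class_counts = counts,
                      n_genes = 20000L, n_informative = 50L * cls,
                      effect_size = 2, noise_sd = 1, seed = seed)
    })
}

#' Write a simulated dataset plus its ground truth
#'
#' Emits the matrix/label CSVs via [write_expression()] and a JSON file
#' recording the informative genes and class mean vectors.
#'
#' @param data a simulated `ExpressionDataset` (with `ground_truth`).
#' @param out_prefix path prefix; writes `<prefix>_matrix.csv`,
#'   `<prefix>_labels.csv`, `<prefix>_truth.json`.
#' @export
write_simulation <- function(data, out_prefix) {
  write_expression(data, paste0(out_prefix, "_matrix.csv"),
                   paste0(out_prefix, "_labels.csv"))
  gt <- attr(data, "ground_truth")
  if (!is.null(gt)) {
    jsonlite::write_json(gt, paste0(out_prefix, "_truth.json"), digits = NA)
  }
  invisible(NULL)
}
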