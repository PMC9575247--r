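# DCGN model: FC + GELU -> reshape to square map -> conv -> max-pool ->
# BiGRU over spatial rows -> conv -> flatten -> 4-layer classifier.
# Parameters live in a flat named list so the optimizer can treat the
# model as a vector of arrays.

#' Build a DCGN model
#'
#' Validates the full shape chain at build time (any inconsistent link is
#' an error naming the broken stage) and initializes all weights with
#' uniform Glorot draws under `config$seed`; biases start at zero.
#'
#' With the default configuration and 20,000 genes the chain is
#' `20000 -> fc(1024, gelu) -> (32,32,1) -> conv(128 kernels, 3x3, stride 2,
#' same) -> (16,16,128) -> maxpool(2x2) -> (8,8,128) -> BiGRU(T=8, F=1024,
#' 64 units/direction) -> (8,128) -> conv(64 kernels, 3x3, stride 2, same)
#' -> (4,64,64) -> flatten -> 128 -> 64 -> 32 -> n_classes` logits.
#'
#' @param config a [dcgn_config()].
#' @param n_genes input feature count.
#' @return a `dcgn_model` object (config, shape chain, parameter list).
#' @export
build_dcgn <- function(config, n_genes) {
  validate_config(config)
  n_genes <- as.integer(n_genes)
  shapes <- dcgn_shapes(config, n_genes)
  set.seed(config$seed)
  ks <- config$kernel_size
  params <- list()
  params$fc_W <- glorot_matrix(n_genes, config$fc_nodes)
  params$fc_b <- numeric(config$fc_nodes)
  params$c1_W <- glorot_conv(ks[1], ks[2], 1L, config$conv1_kernels)
  params$c1_b <- numeric(config$conv1_kernels)
  gin <- shapes$bigru_in[2]
  params <- c(params, prefix_gru(gru_params(gin, config$gru_units,
                                            init = "glorot"), "gf"))
  params <- c(params, prefix_gru(gru_params(gin, config$gru_units,
                                            init = "glorot"), "gb"))
  params$c2_W <- glorot_conv(ks[1], ks[2], 1L, config$conv2_kernels)
  params$c2_b <- numeric(config$conv2_kernels)
  widths <- c(shapes$flat, config$classifier_nodes, config$n_classes)
  for (i in seq_len(4)) {
    params[[paste0("d", i, "_W")]] <- glorot_matrix(widths[i], widths[i + 1])
    params[[paste0("d", i, "_b")]] <- numeric(widths[i + 1])
  }
  structure(list(config = config, n_genes = n_genes, shapes = shapes,
                 params = params),
            class = "dcgn_model")
}

glorot_conv <- function(kh, kw, in_c, n_k) {
  glorot_matrix(kh * kw * in_c, kh * kw * n_k, dims = c(kh, kw, in_c, n_k))
}

prefix_gru <- function(g, pre) {
  out <- list(g$W_z, g$W_r, g$W, g$b_z, g$b_r, g$b)
  names(out) <- paste0(pre, "_", c("Wz", "Wr", "Wc", "bz", "br", "bc"))
  out
}

gather_gru <- function(params, pre, input_size) {
  structure(list(W_z = params[[paste0(pre, "_Wz")]],
                 W_r = params[[paste0(pre, "_Wr")]],
                 W = params[[paste0(pre, "_Wc")]],
                 b_z = params[[paste0(pre, "_bz")]],
                 b_r = params[[paste0(pre, "_br")]],
                 b = params[[paste0(pre, "_bc")]],
                 hidden_size = ncol(params[[paste0(pre, "_Wz")]]),
                 input_size = as.integer(input_size)),
            class = "GRUCellParams")
}

# Shape chain of the network; errors name the stage that breaks.
dcgn_shapes <- function(config, n_genes) {
  side <- as.integer(sqrt(config$fc_nodes))
  s <- config$conv_strides
  ks <- config$kernel_size
  c1_h <- as.integer(ceiling(side / s))
  c1_w <- as.integer(ceiling(side / s))
  ph <- config$pool_size[1]; pw <- config$pool_size[2]
  if (ph > c1_h || pw > c1_w) {
    stop("shape chain broken at max-pool: window ", ph, "x", pw,
         " exceeds conv-1 output ", c1_h, "x", c1_w)
  }
  p_h <- (c1_h - ph) %/% ph + 1L
  p_w <- (c1_w - pw) %/% pw + 1L
  if (config$bigru_axis == "rows") {
    Tlen <- p_h; Fw <- p_w * config$conv1_kernels
  } else {
    Tlen <- p_w; Fw <- p_h * config$conv1_kernels
  }
  if (Tlen < 1) stop("shape chain broken at BiGRU: empty sequence")
  g2 <- 2L * config$gru_units
  c2_h <- as.integer(ceiling(Tlen / s))
  c2_w <- as.integer(ceiling(g2 / s))
  flat <- c2_h * c2_w * config$conv2_kernels
  if (flat < 1) stop("shape chain broken at flatten")
  list(input = n_genes, map = c(side, side, 1L),
       conv1 = c(c1_h, c1_w, config$conv1_kernels),
       pool = c(p_h, p_w, config$conv1_kernels),
       bigru_in = c(Tlen, Fw), bigru_out = c(Tlen, g2),
       conv2 = c(c2_h, c2_w, config$conv2_kernels),
       flat = flat,
       classifier = c(flat, config$classifier_nodes, config$n_classes))
}

#' Total trainable parameter count
#' @param model a `dcgn_model`.
#' @return integer number of scalar parameters.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' @export
print.dcgn_model <- function(x, ...) {
  s <- x$shapes
  cat("dcgn_model:", x$n_genes, "genes ->", x$config$n_classes, "classes,",
      format(n_params(x), big.mark = ","), "parameters\n")
  cat("  ", x$n_genes, "-> fc", x$config$fc_nodes,
      "-> map", paste(s$map, collapse = "x"),
      "-> conv1", paste(s$conv1, collapse = "x"),
      "-> pool", paste(s$pool, collapse = "x"), "\n")
  cat("   -> bigru", paste(s$bigru_out, collapse = "x"),
      "-> conv2", paste(s$conv2, collapse = "x"),
      "-> flat", s$flat, "->",
      paste(s$classifier[-1], collapse = " -> "), "\n")
  invisible(x)
}

# Pooled map -> (N, T, F) sequence for the BiGRU. "rows": time = height,
# per-step features = width x channels (natural array flatten).
map_to_sequence <- function(x, axis) {
  if (axis == "columns") x <- aperm(x, c(1, 3, 2, 4))
  d <- dim(x)
  out <- aperm(x, c(1, 3, 4, 2))          # (N, W, C, H)
  dim(out) <- c(d[1], d[3] * d[4], d[2])  # (N, F, T)
  aperm(out, c(1, 3, 2))                  # (N, T, F)
}

sequence_to_map_bwd <- function(d_seq, xdim, axis) {
  d <- xdim
  if (axis == "columns") d <- d[c(1, 3, 2, 4)]
  g <- aperm(d_seq, c(1, 3, 2))           # (N, F, T)
  dim(g) <- c(d[1], d[3], d[4], d[2])     # (N, W, C, H)
  g <- aperm(g, c(1, 4, 2, 3))            # (N, H, W, C)
  if (axis == "columns") g <- aperm(g, c(1, 3, 2, 4))
  g
}

#' DCGN forward pass
#'
#' Produces raw class scores (logits); no terminal softmax — the softmax is
#' folded into the loss for numerical stability. Dropout is active only
#' when `training = TRUE` (draws come from the current RNG state).
#'
#' @param model a `dcgn_model`.
#' @param x numeric matrix, N x n_genes.
#' @param training logical; enables dropout.
#' @return N x n_classes matrix of logits.
#' @export
dcgn_forward <- function(model, x, training = FALSE) {
  dcgn_forward_cache(model, x, training, keep = FALSE)$logits
}

dcgn_forward_cache <- function(model, x, training = FALSE, keep = TRUE) {
  cfg <- model$config
  p <- model$params
  x <- as.matrix(x)
  if (ncol(x) != model$n_genes) {
    stop("input has ", ncol(x), " genes but model expects ", model$n_genes)
  }
  act <- cfg$activation
  cache <- list()
  fc <- dense_fwd_cache(x, p$fc_W, p$fc_b, act)
  map <- reshape_to_map(fc$out)
  c1 <- conv2d_fwd_cache(map, p$c1_W, cfg$conv_strides, p$c1_b)
  a1_z <- c1$out
  a1 <- activation_apply(act, a1_z)
  pl <- maxpool_fwd_cache(a1, cfg$pool_size, cfg$pool_size[1])
  seqx <- map_to_sequence(pl$out, cfg$bigru_axis)
  gf <- gather_gru(p, "gf", dim(seqx)[3])
  gb <- gather_gru(p, "gb", dim(seqx)[3])
  bg <- bigru_fwd_cache(seqx, gf, gb)
  bg_map <- bg$out
  dim(bg_map) <- c(dim(bg_map)[1], dim(bg_map)[2], dim(bg_map)[3], 1L)
  c2 <- conv2d_fwd_cache(bg_map, p$c2_W, cfg$conv_strides, p$c2_b)
  a2_z <- c2$out
  a2 <- activation_apply(act, a2_z)
  flat <- a2
  dim(flat) <- c(dim(a2)[1], prod(dim(a2)[2:4]))
  rates <- c(cfg$dropout_rates[1], cfg$dropout_rates[1], cfg$dropout_rates[2])
  d_caches <- vector("list", 3)
  h <- flat
  for (i in 1:3) {
    dn <- dense_fwd_cache(h, p[[paste0("d", i, "_W")]],
                          p[[paste0("d", i, "_b")]], act)
    dr <- dropout_fwd(dn$out, rates[i], training)
    d_caches[[i]] <- list(dense = dn, mask = dr$mask)
    h <- dr$out
  }
  out <- dense_fwd_cache(h, p$d4_W, p$d4_b, "linear")
  res <- list(logits = out$out)
  if (keep) {
    res$cache <- list(fc = fc, mapdim = dim(map), c1 = c1, a1_z = a1_z,
                      pl = pl, seqdim = dim(pl$out), bg = bg, c2 = c2,
                      a2_z = a2_z, a2dim = dim(a2), d = d_caches, out = out,
                      act = act, axis = cfg$bigru_axis)
  }
  res
}

# Full backward pass; d_logits is N x C. Returns gradients with the same
# names/shapes as model$params.
dcgn_backward <- function(model, cache, d_logits) {
  act <- cache$act
  g <- list()
  bo <- dense_bwd(cache$out, d_logits)
  g$d4_W <- bo$dW; g$d4_b <- bo$db
  dh <- bo$dx
  for (i in 3:1) {
    dc <- cache$d[[i]]
    if (!is.null(dc$mask)) dh <- dh * dc$mask
    bd <- dense_bwd(dc$dense, dh)
    g[[paste0("d", i, "_W")]] <- bd$dW
    g[[paste0("d", i, "_b")]] <- bd$db
    dh <- bd$dx
  }
  da2 <- dh
  dim(da2) <- cache$a2dim
  dz2 <- da2 * activation_grad(act, cache$a2_z)
  b2 <- conv2d_bwd(cache$c2, dz2)
  g$c2_W <- b2$dW; g$c2_b <- b2$db
  d_bg <- b2$dx
  dim(d_bg) <- dim(d_bg)[1:3]
  bb <- bigru_bwd(cache$bg, d_bg)
  for (nm in names(bb$grads_f)) {
    g[[paste0("gf_", sub("_", "", gru_name_map(nm)))]] <- bb$grads_f[[nm]]
  }
  for (nm in names(bb$grads_b)) {
    g[[paste0("gb_", sub("_", "", gru_name_map(nm)))]] <- bb$grads_b[[nm]]
  }
  d_pool <- sequence_to_map_bwd(bb$dx, cache$seqdim, cache$axis)
  da1 <- maxpool_bwd(cache$pl, d_pool)
  dz1 <- da1 * activation_grad(act, cache$a1_z)
  b1 <- conv2d_bwd(cache$c1, dz1)
  g$c1_W <- b1$dW; g$c1_b <- b1$db
  d_map <- b1$dx
  d_fc <- reshape_to_map_bwd(d_map)
  bf <- dense_bwd(cache$fc, d_fc)
  g$fc_W <- bf$dW; g$fc_b <- bf$db
  g[names(model$params)]
}

gru_name_map <- function(nm) {
  c(W_z = "Wz", W_r = "Wr", W = "Wc", b_z = "bz", b_r = "br", b = "bc")[[nm]]
}

#' Save a trained model to disk
#'
#' Writes a single RDS file holding the config, shapes, weights, the label
#' coding and any attached standardizer, reloadable with [load_dcgn()].
#'
#' @param model a `dcgn_model` (possibly with `$standardizer` and
#'   `$label_levels` attached by [train_dcgn()]).
#' @param path output file path.
#' @export
save_dcgn <- function(model, path) {
  stopifnot(inherits(model, "dcgn_model"))
  saveRDS(model, path, version = 2)
  invisible(NULL)
}

#' Load a model saved with [save_dcgn()]
#' @param path RDS path.
#' @return the `dcgn_model`.
#' @export
load_dcgn <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "dcgn_model"))
  m
}
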