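# Layer primitives for the DCGN network. Every forward function has a
# matching *_backward so the whole network can be trained by hand-written
# reverse-mode differentiation; caches carry exactly what the backward
# pass needs. Image batches are arrays with dim (N, H, W, C).

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Fully connected layer forward pass
#'
#' Computes `activation(x %*% W + b)` for a batch of row vectors.
#'
#' @param x numeric matrix, N x d_in.
#' @param W weight matrix, d_in x d_out.
#' @param b bias vector, length d_out.
#' @param activation an activation name (see [activation_apply()]) or
#'   `"linear"` for no nonlinearity.
#' @return numeric matrix N x d_out.
#' @export
dense_forward <- function(x, W, b, activation = "linear") {
  x <- as.matrix(x)
  if (ncol(x) != nrow(W)) {
    stop("shape mismatch in dense layer: input is ", nrow(x), "x", ncol(x),
         " but weights are ", nrow(W), "x", ncol(W))
  }
  z <- x %*% W
  z <- sweep(z, 2, b, "+")
  if (identical(activation, "linear")) z else activation_apply(activation, z)
}

dense_fwd_cache <- function(x, W, b, activation) {
  z <- sweep(x %*% W, 2, b, "+")
  a <- if (identical(activation, "linear")) z else activation_apply(activation, z)
  list(out = a, x = x, z = z, W = W, activation = activation)
}

dense_bwd <- function(cache, d_out) {
  dz <- if (identical(cache$activation, "linear")) d_out
        else d_out * activation_grad(cache$activation, cache$z)
  list(dx = dz %*% t(cache$W),
       dW = crossprod(cache$x, dz),
       db = colSums(dz))
}

#' Reshape flat FC output to a square single-channel map
#'
#' Row-major: feature `j` of a sample lands at map position
#' (`(j-1) %/% S + 1`, `(j-1) %% S + 1`) where `S = sqrt(fc_nodes)`.
#' A 1024-wide FC output becomes a 32 x 32 x 1 map.
#'
#' @param x numeric matrix N x fc_nodes; fc_nodes must be a perfect square.
#' @return array with dim (N, S, S, 1).
#' @export
reshape_to_map <- function(x) {
  x <- as.matrix(x)
  side <- sqrt(ncol(x))
  if (side != floor(side)) {
    stop(ncol(x), " is not a perfect square; cannot reshape to a map")
  }
  side <- as.integer(side)
  out <- aperm(array(x, c(nrow(x), side, side)), c(1, 3, 2))
  dim(out) <- c(nrow(x), side, side, 1L)
  out
}

reshape_to_map_bwd <- function(d_out) {
  n <- dim(d_out)[1]; side <- dim(d_out)[2]
  d <- d_out
  dim(d) <- c(n, side, side)
  d <- aperm(d, c(1, 3, 2))
  dim(d) <- c(n, side * side)
  d
}

# Output spatial size and padding for "same" convolution:
# out = ceil(in / stride); total pad = max((out-1)*stride + k - in, 0),
# extra padding on the bottom/right when odd.
conv_same_geometry <- function(in_size, k, stride) {
  out <- ceiling(in_size / stride)
  pad <- max((out - 1L) * stride + k - in_size, 0L)
  list(out = as.integer(out), before = as.integer(pad %/% 2),
       after = as.integer(pad - pad %/% 2))
}

pad_nhwc <- function(x, top, bottom, left, right) {
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + top + bottom, d[3] + left + right, d[4]))
  out[, top + seq_len(d[2]), left + seq_len(d[3]), ] <- x
  out
}

# Gather strided kernel-offset slices into the im2col patch matrix:
# rows index (n, oh, ow), columns index (kh fastest, then kw, then channel),
# matching R's flattening of a (kh, kw, C, F) kernel array.
im2col <- function(xpad, kh, kw, stride, out_h, out_w) {
  d <- dim(xpad)
  n <- d[1]; C <- d[4]
  P <- array(0, c(n, out_h, out_w, kh, kw, C))
  for (i in seq_len(kh)) {
    rows <- seq.int(i, by = stride, length.out = out_h)
    for (j in seq_len(kw)) {
      cols <- seq.int(j, by = stride, length.out = out_w)
      P[, , , i, j, ] <- xpad[, rows, cols, , drop = FALSE]
    }
  }
  dim(P) <- c(n * out_h * out_w, kh * kw * C)
  P
}

#' 2-D convolution forward pass ("same" padding)
#'
#' Cross-correlation (no kernel flip, the convention of all modern deep
#' learning frameworks) with zero padding chosen so each spatial output
#' size equals `ceil(input / stride)`; output channels equal the number of
#' kernels.
#'
#' @param x input array, dim (N, H, W, C).
#' @param kernels kernel bank, dim (kh, kw, C, n_kernels).
#' @param stride positive integer stride (both axes).
#' @param bias optional per-kernel bias, length n_kernels (default 0).
#' @return array with dim (N, ceil(H/stride), ceil(W/stride), n_kernels).
#' @export
conv2d_forward <- function(x, kernels, stride = 1L, bias = NULL) {
  conv2d_fwd_cache(x, kernels, stride, bias)$out
}

conv2d_fwd_cache <- function(x, kernels, stride = 1L, bias = NULL) {
  d <- dim(x); kd <- dim(kernels)
  if (length(d) != 4 || length(kd) != 4) {
    stop("conv2d expects a (N,H,W,C) input and (kh,kw,C,F) kernels")
  }
  if (kd[3] != d[4]) {
    stop("kernel channel count (", kd[3], ") != input channels (", d[4], ")")
  }
  gh <- conv_same_geometry(d[2], kd[1], stride)
  gw <- conv_same_geometry(d[3], kd[2], stride)
  xpad <- pad_nhwc(x, gh$before, gh$after, gw$before, gw$after)
  P <- im2col(xpad, kd[1], kd[2], stride, gh$out, gw$out)
  K <- kernels
  dim(K) <- c(kd[1] * kd[2] * kd[3], kd[4])
  out <- P %*% K
  if (!is.null(bias)) out <- sweep(out, 2, bias, "+")
  dim(out) <- c(d[1], gh$out, gw$out, kd[4])
  list(out = out, P = P, xdim = d, paddim = dim(xpad), kdim = kd,
       kernels_mat = K, stride = stride, gh = gh, gw = gw)
}

conv2d_bwd <- function(cache, d_out) {
  kd <- cache$kdim
  n_out <- prod(dim(d_out)[1:3])
  dmat <- d_out
  dim(dmat) <- c(n_out, kd[4])
  dK <- crossprod(cache$P, dmat)
  dim(dK) <- kd
  db <- colSums(dmat)
  dP <- dmat %*% t(cache$kernels_mat)
  dim(dP) <- c(dim(d_out)[1], cache$gh$out, cache$gw$out, kd[1], kd[2], kd[3])
  dxpad <- array(0, cache$paddim)
  for (i in seq_len(kd[1])) {
    rows <- seq.int(i, by = cache$stride, length.out = cache$gh$out)
    for (j in seq_len(kd[2])) {
      cols <- seq.int(j, by = cache$stride, length.out = cache$gw$out)
      sl <- dP[, , , i, j, , drop = FALSE]
      dim(sl) <- c(dim(d_out)[1], cache$gh$out, cache$gw$out, kd[3])
      dxpad[, rows, cols, ] <- dxpad[, rows, cols, , drop = FALSE] + sl
    }
  }
  d <- cache$xdim
  dx <- dxpad[, cache$gh$before + seq_len(d[2]),
              cache$gw$before + seq_len(d[3]), , drop = FALSE]
  list(dx = dx, dW = dK, db = db)
}

#' Max-pooling forward pass
#'
#' Per-channel windowed maximum; channel count is unchanged. No padding:
#' output spatial size is `floor((in - pool) / stride) + 1`.
#'
#' @param x input array, dim (N, H, W, C).
#' @param pool length-2 window size.
#' @param stride positive integer stride; defaults to the window height.
#' @return pooled array.
#' @export
maxpool_forward <- function(x, pool = c(2L, 2L), stride = pool[1]) {
  maxpool_fwd_cache(x, pool, stride)$out
}

maxpool_fwd_cache <- function(x, pool = c(2L, 2L), stride = pool[1]) {
  d <- dim(x)
  ph <- pool[1]; pw <- pool[2]
  if (ph > d[2] || pw > d[3]) {
    stop("pool window (", ph, "x", pw, ") larger than input (",
         d[2], "x", d[3], ")")
  }
  out_h <- (d[2] - ph) %/% stride + 1L
  out_w <- (d[3] - pw) %/% stride + 1L
  n_cell <- d[1] * out_h * out_w * d[4]
  cand <- matrix(0, n_cell, ph * pw)
  for (i in seq_len(ph)) {
    rows <- seq.int(i, by = stride, length.out = out_h)
    for (j in seq_len(pw)) {
      cols <- seq.int(j, by = stride, length.out = out_w)
      sl <- x[, rows, cols, , drop = FALSE]
      cand[, i + (j - 1L) * ph] <- as.vector(sl)
    }
  }
  arg <- max.col(cand, ties.method = "first")
  out <- cand[cbind(seq_len(n_cell), arg)]
  dim(out) <- c(d[1], out_h, out_w, d[4])
  list(out = out, arg = arg, xdim = d, pool = c(ph, pw), stride = stride,
       out_h = out_h, out_w = out_w)
}

maxpool_bwd <- function(cache, d_out) {
  d <- cache$xdim
  ph <- cache$pool[1]; pw <- cache$pool[2]
  dx <- array(0, d)
  dvec <- as.vector(d_out)
  for (i in seq_len(ph)) {
    rows <- seq.int(i, by = cache$stride, length.out = cache$out_h)
    for (j in seq_len(pw)) {
      cols <- seq.int(j, by = cache$stride, length.out = cache$out_w)
      sel <- cache$arg == (i + (j - 1L) * ph)
      if (!any(sel)) next
      g <- array(0, c(d[1], cache$out_h, cache$out_w, d[4]))
      g[sel] <- dvec[sel]
      dx[, rows, cols, ] <- dx[, rows, cols, , drop = FALSE] + g
    }
  }
  dx
}

#' One GRU cell step
#'
#' Gates follow the standard update/reset formulation: with the
#' concatenation `[h_prev, x_t]`,
#' `z = sigmoid(W_z [h,x] + b_z)`, `r = sigmoid(W_r [h,x] + b_r)`,
#' candidate `h' = tanh(W [r * h, x] + b)`, and the new state
#' `h_t = (1 - z) * h' + z * h_prev`.
#'
#' @param x_t input: numeric vector (length F) or N x F matrix.
#' @param h_prev previous hidden state: vector (length H) or N x H matrix.
#' @param params a [gru_params()] list with `W_z`, `W_r`, `W` of dim
#'   (H + F) x H and biases `b_z`, `b_r`, `b` of length H.
#' @return the new hidden state, same shape convention as `h_prev`.
#' @export
gru_cell_step <- function(x_t, h_prev, params) {
  vec_in <- is.null(dim(x_t))
  if (vec_in) {
    x_t <- matrix(x_t, nrow = 1)
    h_prev <- matrix(h_prev, nrow = 1)
  }
  st <- gru_step_cache(x_t, h_prev, params)
  if (vec_in) drop(st$h) else st$h
}

gru_step_cache <- function(x_t, h_prev, params) {
  H <- params$hidden_size
  if (ncol(h_prev) != H || ncol(x_t) + H != nrow(params$W_z)) {
    stop("GRU shape mismatch: input ", ncol(x_t), ", hidden ", ncol(h_prev),
         ", weights expect input ", nrow(params$W_z) - H)
  }
  conc <- cbind(h_prev, x_t)
  z <- sigmoid(sweep(conc %*% params$W_z, 2, params$b_z, "+"))
  r <- sigmoid(sweep(conc %*% params$W_r, 2, params$b_r, "+"))
  conc_c <- cbind(h_prev * r, x_t)
  hc <- tanh(sweep(conc_c %*% params$W, 2, params$b, "+"))
  h <- (1 - z) * hc + z * h_prev
  list(h = h, z = z, r = r, hc = hc, h_prev = h_prev, x = x_t)
}

#' Construct a GRU parameter set
#'
#' @param input_size F, the per-step feature width.
#' @param hidden_size H, the hidden-state width.
#' @param init `"zero"` or `"glorot"`; glorot draws are controlled by the
#'   caller's RNG state.
#' @return a `GRUCellParams` list (`W_z`, `W_r`, `W`, `b_z`, `b_r`, `b`,
#'   `hidden_size`, `input_size`).
#' @export
gru_params <- function(input_size, hidden_size, init = "zero") {
  mk <- function() {
    if (init == "glorot") glorot_matrix(input_size + hidden_size, hidden_size)
    else matrix(0, input_size + hidden_size, hidden_size)
  }
  structure(list(W_z = mk(), W_r = mk(), W = mk(),
                 b_z = numeric(hidden_size), b_r = numeric(hidden_size),
                 b = numeric(hidden_size),
                 hidden_size = as.integer(hidden_size),
                 input_size = as.integer(input_size)),
            class = "GRUCellParams")
}

glorot_matrix <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dims)
}

# Run a GRU over a (N, T, F) batch of sequences in one direction.
gru_seq_forward <- function(x, params, reverse = FALSE) {
  d <- dim(x)
  n <- d[1]; Tlen <- d[2]
  H <- params$hidden_size
  h <- matrix(0, n, H)
  steps <- if (reverse) rev(seq_len(Tlen)) else seq_len(Tlen)
  out <- array(0, c(n, Tlen, H))
  caches <- vector("list", Tlen)
  for (t in steps) {
    xt <- x[, t, , drop = FALSE]
    dim(xt) <- c(n, d[3])
    st <- gru_step_cache(xt, h, params)
    h <- st$h
    out[, t, ] <- h
    caches[[t]] <- st
  }
  list(out = out, caches = caches, reverse = reverse, params = params,
       xdim = d)
}

# Backpropagation through time for one direction; returns dx and the
# parameter gradients.
gru_seq_backward <- function(fwd, d_out) {
  p <- fwd$params
  d <- fwd$xdim
  n <- d[1]; Tlen <- d[2]; Fw <- d[3]; H <- p$hidden_size
  g <- list(W_z = matrix(0, H + Fw, H), W_r = matrix(0, H + Fw, H),
            W = matrix(0, H + Fw, H), b_z = numeric(H), b_r = numeric(H),
            b = numeric(H))
  dx <- array(0, d)
  dh_next <- matrix(0, n, H)
  steps <- if (fwd$reverse) seq_len(Tlen) else rev(seq_len(Tlen))
  for (t in steps) {
    st <- fwd$caches[[t]]
    dh <- dh_next
    dh <- dh + array(d_out[, t, ], c(n, H))
    dhc <- dh * (1 - st$z)
    dz <- dh * (st$h_prev - st$hc)
    dh_prev <- dh * st$z
    dac <- dhc * (1 - st$hc^2)
    dconc_c <- dac %*% t(p$W)
    d_rh <- dconc_c[, seq_len(H), drop = FALSE]
    dxt <- dconc_c[, H + seq_len(Fw), drop = FALSE]
    dr <- d_rh * st$h_prev
    dh_prev <- dh_prev + d_rh * st$r
    daz <- dz * st$z * (1 - st$z)
    dar <- dr * st$r * (1 - st$r)
    dconc_g <- daz %*% t(p$W_z) + dar %*% t(p$W_r)
    dh_prev <- dh_prev + dconc_g[, seq_len(H), drop = FALSE]
    dxt <- dxt + dconc_g[, H + seq_len(Fw), drop = FALSE]
    conc_g <- cbind(st$h_prev, st$x)
    conc_c <- cbind(st$h_prev * st$r, st$x)
    g$W_z <- g$W_z + crossprod(conc_g, daz)
    g$W_r <- g$W_r + crossprod(conc_g, dar)
    g$W <- g$W + crossprod(conc_c, dac)
    g$b_z <- g$b_z + colSums(daz)
    g$b_r <- g$b_r + colSums(dar)
    g$b <- g$b + colSums(dac)
    dx[, t, ] <- dxt
    dh_next <- dh_prev
  }
  list(dx = dx, grads = g)
}

#' Bidirectional GRU forward pass
#'
#' Runs a forward GRU left-to-right and a backward GRU right-to-left, both
#' from zero initial state, and concatenates the two hidden states at each
#' time step.
#'
#' @param sequence a single T x F matrix or an (N, T, F) array.
#' @param fwd,bwd `GRUCellParams` for the two directions.
#' @return T x 2H matrix (single sequence) or (N, T, 2H) array.
#' @export
bigru_forward <- function(sequence, fwd, bwd) {
  single <- length(dim(sequence)) == 2
  x <- sequence
  if (single) {
    x <- array(sequence, c(1, nrow(sequence), ncol(sequence)))
  }
  if (dim(x)[2] < 1) stop("empty sequence")
  f <- gru_seq_forward(x, fwd, reverse = FALSE)
  b <- gru_seq_forward(x, bwd, reverse = TRUE)
  H <- fwd$hidden_size
  out <- array(0, c(dim(x)[1], dim(x)[2], 2L * H))
  out[, , seq_len(H)] <- f$out
  out[, , H + seq_len(bwd$hidden_size)] <- b$out
  if (single) {
    out <- array(out, dim(out)[2:3])
  }
  out
}

bigru_fwd_cache <- function(x, fwd, bwd) {
  f <- gru_seq_forward(x, fwd, reverse = FALSE)
  b <- gru_seq_forward(x, bwd, reverse = TRUE)
  H <- fwd$hidden_size
  out <- array(0, c(dim(x)[1], dim(x)[2], H + bwd$hidden_size))
  out[, , seq_len(H)] <- f$out
  out[, , H + seq_len(bwd$hidden_size)] <- b$out
  list(out = out, f = f, b = b, H = H)
}

bigru_bwd <- function(cache, d_out) {
  H <- cache$H
  H2 <- dim(d_out)[3] - H
  gf <- gru_seq_backward(cache$f, d_out[, , seq_len(H), drop = FALSE])
  gb <- gru_seq_backward(cache$b, d_out[, , H + seq_len(H2), drop = FALSE])
  list(dx = gf$dx + gb$dx, grads_f = gf$grads, grads_b = gb$grads)
}

# Inverted dropout: scale kept units by 1/(1-rate) so inference needs no
# rescaling. Returns the mask for the backward pass.
dropout_fwd <- function(x, rate, training) {
  if (!training || rate == 0) {
    return(list(out = x, mask = NULL))
  }
  mask <- (matrix(stats::runif(length(x)), nrow(x)) >= rate) / (1 - rate)
  list(out = x * mask, mask = mask)
}
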