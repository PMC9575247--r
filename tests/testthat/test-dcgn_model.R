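test_that("dense layer computes activation(xW + b)", {
  x <- matrix(c(1, 2, 3, 0.5, -1, 2), 2, byrow = TRUE)
  W <- diag(3)
  expect_equal(dense_forward(abs(x), W, rep(0, 3), "relu"), abs(x))
  # scalar hand computation through the tanh-approximate gelu
  x1 <- matrix(c(0.3, -0.7), 1)
  W1 <- matrix(c(2, 0.5), 2, 1)
  b1 <- 0.1
  z <- 0.3 * 2 + (-0.7) * 0.5 + 0.1
  hand <- 0.5 * z * (1 + tanh(sqrt(2 / pi) * (z + 0.044715 * z^3)))
  expect_equal(dense_forward(x1, W1, b1, "gelu_approx")[1, 1], hand,
               tolerance = 1e-12)
  # batch dimension preserved
  xb <- matrix(rnorm(15), 5)
  expect_equal(nrow(dense_forward(xb, W, rep(1, 3), "tanh")), 5)
  expect_error(dense_forward(xb, matrix(0, 4, 2), 1:2), "shape mismatch")
})

test_that("reshape to map is row-major with square side", {
  x <- matrix(1:32, 2, 16, byrow = TRUE)
  m <- reshape_to_map(x)
  expect_equal(dim(m), c(2, 4, 4, 1))
  # feature j of sample 1 sits at (row (j-1) %/% 4 + 1, col (j-1) %% 4 + 1)
  expect_equal(m[1, 1, , 1], c(1, 2, 3, 4))
  expect_equal(m[1, 2, , 1], c(5, 6, 7, 8))
  expect_equal(m[2, 4, 4, 1], 32)
  big <- matrix(rnorm(1024), 1)
  expect_equal(dim(reshape_to_map(big)), c(1, 32, 32, 1))
  expect_error(reshape_to_map(matrix(0, 1, 1000)), "not a perfect square")
  # backward inverts forward exactly
  g <- dcgn:::reshape_to_map_bwd(m)
  expect_equal(g, x, ignore_attr = TRUE)
})

test_that("same-padding convolution follows ceil(in/stride) and hand cases", {
  set.seed(1)
  x <- array(rnorm(2 * 32 * 32), c(2, 32, 32, 1))
  k <- array(rnorm(3 * 3 * 128), c(3, 3, 1, 128))
  expect_equal(dim(conv2d_forward(x, k, stride = 2)), c(2, 16, 16, 128))

  # 1x1 unit kernel, stride 1: identity
  xi <- array(rnorm(3 * 4 * 5 * 2), c(3, 4, 5, 2))
  k1 <- array(c(1, 0, 0, 1), c(1, 1, 2, 2))
  expect_equal(conv2d_forward(xi, k1, 1), xi, tolerance = 1e-12)

  # all-ones 3x3 kernel on an all-ones 3x3 image: center 9, corners 4
  xo <- array(1, c(1, 3, 3, 1))
  ko <- array(1, c(3, 3, 1, 1))
  out <- conv2d_forward(xo, ko, 1)
  expect_equal(out[1, 2, 2, 1], 9)
  expect_equal(out[1, 1, 1, 1], 4)
  expect_equal(out[1, 1, 2, 1], 6)

  expect_error(conv2d_forward(xi, array(0, c(3, 3, 3, 1)), 1), "channel")
})

test_that("convolution matches the naive quadruple-loop oracle", {
  set.seed(42)
  for (case in 1:6) {
    h <- sample(3:8, 1); w <- sample(3:8, 1); C <- sample(1:2, 1)
    nk <- sample(1:4, 1); s <- sample(1:2, 1)
    x <- array(rnorm(2 * h * w * C), c(2, h, w, C))
    k <- array(rnorm(3 * 3 * C * nk), c(3, 3, C, nk))
    b <- rnorm(nk)
    expect_equal(conv2d_forward(x, k, s, b), oracle_conv2d(x, k, s, b),
                 tolerance = 1e-6)
  }
})

test_that("max pooling takes windowed maxima and keeps channels", {
  x <- array(c(1, 3, 2, 4), c(1, 2, 2, 1))
  expect_equal(as.vector(maxpool_forward(x, c(2, 2), 2)), 4)
  const <- array(2.5, c(2, 4, 4, 3))
  expect_true(all(maxpool_forward(const) == 2.5))
  big <- array(rnorm(16 * 16 * 8), c(1, 16, 16, 8))
  expect_equal(dim(maxpool_forward(big)), c(1, 8, 8, 8))
  expect_error(maxpool_forward(array(0, c(1, 1, 1, 1)), c(2, 2)), "larger")
})

test_that("GRU cell matches the scalar-loop oracle and closed forms", {
  # all-zero weights: z = r = 0.5, candidate 0, h = 0.5 * h_prev
  p0 <- gru_params(3, 2)
  h <- c(0.4, -0.8)
  expect_equal(gru_cell_step(c(1, 2, 3), h, p0), 0.5 * h, tolerance = 1e-12)

  set.seed(8)
  for (i in 1:20) {
    H <- sample(1:4, 1); Fw <- sample(1:4, 1)
    p <- gru_params(Fw, H)
    p$W_z[] <- rnorm(length(p$W_z)); p$W_r[] <- rnorm(length(p$W_r))
    p$W[] <- rnorm(length(p$W))
    p$b_z <- rnorm(H); p$b_r <- rnorm(H); p$b <- rnorm(H)
    x <- rnorm(Fw); hp <- rnorm(H)
    expect_equal(gru_cell_step(x, hp, p), oracle_gru_step(x, hp, p),
                 tolerance = 1e-9)
  }

  # z forced to 1 keeps the old state
  pz <- gru_params(2, 2)
  pz$b_z <- rep(50, 2)
  hp <- c(0.3, -0.6)
  expect_equal(gru_cell_step(c(1, -1), hp, pz), hp, tolerance = 1e-9)

  expect_error(gru_cell_step(1:5, c(0, 0), gru_params(3, 2)), "mismatch")
})

test_that("BiGRU concatenates direction-wise states with the right symmetry", {
  set.seed(3)
  mk <- function(Fw, H) {
    p <- gru_params(Fw, H)
    p$W_z[] <- rnorm(length(p$W_z)); p$W_r[] <- rnorm(length(p$W_r))
    p$W[] <- rnorm(length(p$W))
    p
  }
  fwd <- mk(3, 2); bwd <- mk(3, 2)
  # T = 1 reduces to two single steps from zero state
  x1 <- matrix(rnorm(3), 1)
  out1 <- bigru_forward(x1, fwd, bwd)
  expect_equal(out1[1, 1:2], gru_cell_step(x1[1, ], c(0, 0), fwd),
               tolerance = 1e-12)
  expect_equal(out1[1, 3:4], gru_cell_step(x1[1, ], c(0, 0), bwd),
               tolerance = 1e-12)

  # reversing time and swapping directions reverses output, halves swapped
  x <- matrix(rnorm(5 * 3), 5)
  out <- bigru_forward(x, fwd, bwd)
  rev_out <- bigru_forward(x[5:1, ], bwd, fwd)
  expect_equal(rev_out[5:1, c(3, 4, 1, 2)], out, tolerance = 1e-12,
               ignore_attr = TRUE)

  # zero everything stays zero
  z <- bigru_forward(matrix(0, 4, 3), gru_params(3, 2), gru_params(3, 2))
  expect_true(all(z == 0))

  expect_error(bigru_forward(array(0, c(2, 0, 3)), fwd, bwd), "empty")
})

test_that("model build validates the shape chain and is seed-deterministic", {
  cfg <- dcgn_config(n_classes = 10L)
  m <- build_dcgn(cfg, 2000L)
  s <- m$shapes
  expect_equal(s$map, c(32L, 32L, 1L))
  expect_equal(s$conv1, c(16L, 16L, 128L))
  expect_equal(s$pool, c(8L, 8L, 128L))
  expect_equal(s$bigru_in, c(8L, 1024L))
  expect_equal(s$bigru_out, c(8L, 128L))
  expect_equal(s$conv2, c(4L, 64L, 64L))
  expect_equal(s$classifier, c(4L * 64L * 64L, 128L, 64L, 32L, 10L))
  expect_equal(ncol(m$params$d4_W), 10L)

  m2 <- build_dcgn(cfg, 2000L)
  expect_identical(m$params, m2$params)

  # closed-form parameter count from the shape chain
  g_in <- 1024L + 64L
  expected <- 2000 * 1024 + 1024 +               # fc
    3 * 3 * 1 * 128 + 128 +                      # conv1
    2 * (3 * (g_in * 64 + 64)) +                 # two GRU directions
    3 * 3 * 1 * 64 + 64 +                        # conv2
    16384 * 128 + 128 + 128 * 64 + 64 +          # classifier 1-2
    64 * 32 + 32 + 32 * 10 + 10                  # classifier 3-4
  expect_equal(n_params(m), expected)
})

test_that("forward pass contract: shape, finiteness, equivariance", {
  cfg <- tiny_net_config()
  m <- build_dcgn(cfg, 12L)
  set.seed(5)
  x <- matrix(rnorm(6 * 12), 6)
  out <- dcgn_forward(m, x)
  expect_equal(dim(out), c(6L, 3L))
  expect_true(all(is.finite(out)))
  # inference is deterministic (no dropout noise)
  expect_identical(out, dcgn_forward(m, x))
  # permuting rows permutes outputs identically
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(dcgn_forward(m, x[perm, ]), out[perm, ], tolerance = 1e-12)
  # dropout rates 0 + training = TRUE equals inference exactly
  expect_equal(dcgn_forward(m, x, training = TRUE), out)
  expect_error(dcgn_forward(m, x[, 1:5]), "genes")
})

test_that("dropout is active in training mode and scales correctly", {
  cfg <- tiny_net_config()
  cfg$dropout_rates <- c(0.5, 0.5)
  m <- build_dcgn(cfg, 12L)
  set.seed(1)
  x <- matrix(rnorm(8 * 12), 8)
  inf <- dcgn_forward(m, x, training = FALSE)
  set.seed(2)
  tr1 <- dcgn_forward(m, x, training = TRUE)
  set.seed(2)
  tr2 <- dcgn_forward(m, x, training = TRUE)
  set.seed(3)
  tr3 <- dcgn_forward(m, x, training = TRUE)
  expect_identical(tr1, tr2)          # same RNG state, same masks
  expect_false(isTRUE(all.equal(tr1, tr3)))  # different masks differ
  expect_false(isTRUE(all.equal(tr1, inf)))
})

test_that("models serialize and reload intact", {
  path <- withr::local_tempfile(fileext = ".rds")
  m <- build_dcgn(tiny_net_config(), 12L)
  save_dcgn(m, path)
  m2 <- load_dcgn(path)
  expect_identical(m$params, m2$params)
  set.seed(4)
  x <- matrix(rnorm(3 * 12), 3)
  expect_identical(dcgn_forward(m, x), dcgn_forward(m2, x))
})
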