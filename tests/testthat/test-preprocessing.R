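test_that("minority classes are those strictly below the 15% cutoff", {
  # imbalance echoing a 2133-sample breast-cancer cohort: cutoff 319.95
  labels <- rep(0:3, c(1060, 721, 202, 150))
  expect_equal(identify_minority_classes(labels, 0.15), c(2L, 3L))
  # balanced data has no minority
  expect_length(identify_minority_classes(rep(0:2, each = 50), 0.15), 0)
  # boundary: count == cutoff exactly is excluded (strict <)
  expect_length(identify_minority_classes(rep(0:1, c(85, 15)), 0.15), 0)
  expect_error(identify_minority_classes(integer(0)), "empty")
})

test_that("SMOTE interpolates on segments to same-class k-NN neighbours", {
  ds <- make_labeled_dataset(c(60, 12), n_genes = 6, seed = 4)
  out <- smote_oversample(ds, k = 5, threshold = 0.2, seed = 21)
  counts <- table(out$labels)
  expect_equal(as.integer(counts), c(60L, 60L))
  expect_equal(sum(out$synthetic_mask), 48L)
  # original rows unchanged, in place
  n0 <- nrow(ds$values)
  expect_equal(out$values[seq_len(n0), ], ds$values, ignore_attr = TRUE)
  expect_false(any(out$synthetic_mask[seq_len(n0)]))
  # each synthetic row lies on a segment [x_i, x_n] with x_n among the
  # exhaustively computed 5 nearest same-class neighbours of some x_i
  minority <- ds$values[ds$labels == 1L, ]
  nn <- oracle_knn(minority, 5)
  synth <- out$values[out$synthetic_mask, , drop = FALSE]
  expect_true(all(out$labels[out$synthetic_mask] == 1L))
  on_valid_segment <- function(srow) {
    for (i in seq_len(nrow(minority))) {
      for (j in nn[i, ]) {
        lo <- pmin(minority[i, ], minority[j, ])
        hi <- pmax(minority[i, ], minority[j, ])
        if (all(srow >= lo - 1e-12 & srow <= hi + 1e-12)) {
          # must also be collinear with the endpoints
          d <- minority[j, ] - minority[i, ]
          t_est <- (srow - minority[i, ])[which.max(abs(d))] /
            d[which.max(abs(d))]
          if (max(abs(srow - (minority[i, ] + t_est * d))) < 1e-9) {
            return(TRUE)
          }
        }
      }
    }
    FALSE
  }
  expect_true(all(apply(synth, 1, on_valid_segment)))
})

test_that("SMOTE degenerate and error cases behave", {
  # identical minority points: every synthetic row equals that point
  p <- c(2, -1, 3)
  vals <- rbind(matrix(rnorm(30), 10), matrix(rep(p, 4), 4, byrow = TRUE))
  ds <- expression_dataset(vals, labels = rep(0:1, c(10, 4)),
                           label_levels = c("maj", "min"))
  out <- smote_oversample(ds, k = 3, threshold = 0.4, seed = 2)
  synth <- out$values[out$synthetic_mask, , drop = FALSE]
  expect_true(nrow(synth) == 6)
  expect_true(all(abs(sweep(synth, 2, p)) < 1e-12))

  expect_error(smote_oversample(ds, k = 0), "positive")
  single <- expression_dataset(matrix(rnorm(22), 11),
                               labels = rep(0:1, c(10, 1)),
                               label_levels = c("a", "b"))
  expect_error(smote_oversample(single, threshold = 0.3), "single member")
})

test_that("SMOTE is reproducible and leaves non-minority classes alone", {
  ds <- make_labeled_dataset(c(50, 20, 8), n_genes = 4, seed = 6)
  a <- smote_oversample(ds, seed = 9, threshold = 0.3)
  b <- smote_oversample(ds, seed = 9, threshold = 0.3)
  expect_identical(a$values, b$values)
  counts <- table(a$labels)
  expect_equal(as.integer(counts), c(50L, 50L, 50L))
})

test_that("random undersampling forces counts and is seed-deterministic", {
  ds <- make_labeled_dataset(c(100, 10), n_genes = 3, seed = 5)
  out <- random_undersample(ds, 10, seed = 3)
  expect_equal(as.integer(table(out$labels)), c(10L, 10L))
  # sampling n from n keeps the class as a set
  expect_setequal(out$sample_ids[out$labels == 1L],
                  ds$sample_ids[ds$labels == 1L])
  out2 <- random_undersample(ds, 10, seed = 3)
  expect_identical(out$sample_ids, out2$sample_ids)
  err <- expect_error(random_undersample(ds, 11))
  expect_match(conditionMessage(err), "B")
})

test_that("standardizer uses population sd and inverts exactly", {
  two <- expression_dataset(matrix(c(1, 3, 5, 5), 2),
                            labels = 0:1, label_levels = c("x", "y"))
  p <- fit_standardizer(two)
  expect_equal(unname(p$mean[1]), 2)
  expect_equal(unname(p$std[1]), 1)    # sqrt(((1-2)^2+(3-2)^2)/2)
  expect_equal(unname(p$std[2]), 0)    # constant column

  ds <- make_labeled_dataset(c(20, 20), n_genes = 6, seed = 8)
  ds$values[, 6] <- 4.2               # constant gene
  fitted <- fit_standardizer(ds)
  z <- apply_standardizer(ds, fitted)
  expect_true(all(abs(colMeans(z$values[, 1:5])) < 1e-9))
  popsd <- sqrt(colMeans(sweep(z$values[, 1:5], 2,
                               colMeans(z$values[, 1:5]))^2))
  expect_true(all(abs(popsd - 1) < 1e-9))
  expect_true(all(z$values[, 6] == 0))

  # params fitted on A applied to B invert algebraically
  b <- make_labeled_dataset(c(10, 10), n_genes = 6, seed = 99)
  zb <- apply_standardizer(b, fitted)
  recovered <- sweep(sweep(zb$values[, 1:5], 2, fitted$std[1:5], "*"),
                     2, fitted$mean[1:5], "+")
  expect_equal(recovered, b$values[, 1:5], tolerance = 1e-12,
               ignore_attr = TRUE)

  # standardize then refit: idempotent
  refit <- fit_standardizer(z)
  z2 <- apply_standardizer(z, refit)
  expect_equal(z2$values, z$values, tolerance = 1e-9)

  one <- expression_dataset(matrix(1:2, 1), labels = 0L,
                            label_levels = c("a", "b"))
  expect_error(fit_standardizer(one), "at least 2")
  expect_error(apply_standardizer(ds, read_from <- structure(
    list(mean = 1, std = 1), class = "StandardizationParams")), "genes")
})

test_that("standardizer round-trips through JSON", {
  ds <- make_labeled_dataset(c(5, 5), n_genes = 4, seed = 2)
  p <- fit_standardizer(ds)
  path <- withr::local_tempfile(fileext = ".json")
  write_standardizer(p, path)
  p2 <- read_standardizer(path)
  expect_equal(p2$mean, unname(p$mean), tolerance = 1e-12)
  expect_equal(p2$std, unname(p$std), tolerance = 1e-12)
})

test_that("splits follow floor/floor/remainder and partition the data", {
  ds <- make_labeled_dataset(c(50, 50), n_genes = 3, seed = 7)
  parts <- split_dataset(ds, c(0.8, 0.1, 0.1), seed = 1)
  expect_equal(vapply(parts, function(p) nrow(p$values), integer(1)),
               c(train = 80L, validation = 10L, test = 10L))
  all_ids <- unlist(lapply(parts, `[[`, "sample_ids"))
  expect_setequal(all_ids, ds$sample_ids)
  expect_equal(length(all_ids), length(unique(all_ids)))

  # global floor rule at the published cohort size
  big <- expression_dataset(matrix(rnorm(4221 * 2), 4221),
                            labels = rep(0:1, c(2200, 2021)),
                            label_levels = c("a", "b"))
  p2 <- split_dataset(big, c(0.8, 0.1, 0.1), seed = 2, stratified = FALSE)
  expect_equal(vapply(p2, function(p) nrow(p$values), integer(1)),
               c(train = 3376L, validation = 422L, test = 423L))

  # stratified split preserves class shares to rounding
  p3 <- split_dataset(ds, seed = 5, stratified = TRUE)
  expect_equal(as.integer(table(p3$train$labels)), c(40L, 40L))

  # deterministic under seed
  p4 <- split_dataset(ds, seed = 5, stratified = TRUE)
  expect_identical(p3$train$sample_ids, p4$train$sample_ids)

  expect_error(split_dataset(ds, c(0.5, 0.3, 0.2) + 0.1), "sum to 1")
  tiny <- make_labeled_dataset(c(3, 3), seed = 1)
  expect_error(split_dataset(tiny, c(0.8, 0.1, 0.1), seed = 1), "empty")
})
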