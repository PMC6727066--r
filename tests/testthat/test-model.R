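test_that("parameter initialisation is seeded, shaped, and variance-scaled", {
  p1 <- init_params(24, 8, seed = 5)
  p2 <- init_params(24, 8, seed = 5)
  expect_identical(p1, p2)
  p3 <- init_params(24, 8, seed = 6)
  expect_false(identical(p1$W_e, p3$W_e))
  expect_equal(dim(p1$W_e), c(24, 8))
  expect_equal(dim(p1$W_d), c(8, 8))
  expect_equal(p1$B_e, numeric(8))
})

test_that("encoder applies the affine map then ReLU and splits node blocks", {
  params <- list(W_e = matrix(0, 2, 3), B_e = numeric(3),
                 W_d = diag(3), n_latent = 3L)
  out <- encode(matrix(rnorm(8), 4, 2), params, n_lnc = 2)
  expect_equal(out$E, matrix(0, 4, 3))

  # negative pre-activations clamp to zero: Z = [-1, 2] -> E = [0, 2]
  params$W_e <- matrix(c(-1, 0, 2, 0), 2, 2)
  params$B_e <- numeric(2)
  out <- encode(matrix(c(1, 0), 1, 2), params, n_lnc = 1)
  expect_equal(out$Z, matrix(c(-1, 2), 1, 2))
  expect_equal(out$E, matrix(c(0, 2), 1, 2))

  # hand computation with bias
  params <- list(W_e = matrix(c(1, 1), 2, 1), B_e = 0.5, W_d = matrix(1),
                 n_latent = 1L)
  out <- encode(matrix(c(1, 2), 1, 2), params, n_lnc = 1)
  expect_equal(out$E, matrix(3.5))

  expect_error(encode(matrix(0, 1, 3), params, 1), "feature dimension")
})

test_that("bilinear decoder matches hand cases and the triple-loop oracle", {
  E_l <- matrix(c(1, 0), 1, 2)
  E_m <- matrix(c(0, 1), 1, 2)
  expect_equal(decode(E_l, E_m, diag(2)), matrix(0))
  expect_equal(decode(E_l, E_m, matrix(c(0, 0, 1, 0), 2, 2)), matrix(1))

  set.seed(21)
  for (trial in 1:5) {
    n_l <- sample(1:10, 1); n_m <- sample(1:10, 1); k <- sample(1:5, 1)
    E_l <- matrix(rnorm(n_l * k), n_l, k)
    E_m <- matrix(rnorm(n_m * k), n_m, k)
    W_d <- matrix(rnorm(k * k), k, k)
    Mp <- decode(E_l, E_m, W_d)
    loop <- matrix(0, n_l, n_m)
    for (i in seq_len(n_l)) for (j in seq_len(n_m)) {
      for (a in seq_len(k)) for (b in seq_len(k)) {
        loop[i, j] <- loop[i, j] + E_l[i, a] * W_d[a, b] * E_m[j, b]
      }
    }
    expect_equal(Mp, loop, tolerance = 1e-10)
  }
  expect_error(decode(matrix(0, 1, 2), matrix(0, 1, 3), diag(2)), "dimension")
})

test_that("negative sampling hits the requested count, stays off positives, caps", {
  M <- matrix(0, 4, 4)
  M[1:8] <- 1  # 8 positives, 8 zeros
  expect_equal(sum(sample_negatives(M, 0)), 0)
  set.seed(1)
  om <- sample_negatives(M, 0.5)  # wants 4 of the 8 zeros
  expect_equal(sum(om), 4)
  expect_equal(sum(om * M), 0)
  expect_warning(om_cap <- sample_negatives(M, 10), "capping")
  expect_equal(sum(om_cap), 8)

  # exactly round(p * n_pos) when enough zeros exist
  M2 <- matrix(0, 10, 10); M2[1:8] <- 1
  set.seed(2)
  expect_equal(sum(sample_negatives(M2, 3)), 24)
})

test_that("masked loss matches hand-computed fixtures", {
  zero_params <- list(W_e = matrix(0, 2, 2), B_e = numeric(2),
                      W_d = matrix(0, 2, 2))
  M <- matrix(c(1, 0), 1, 2)
  # perfect reconstruction on the mask, zero parameters: loss 0
  lv <- compute_loss(M, M, omega_p = matrix(c(1, 0), 1, 2),
                     omega_n = matrix(c(0, 1), 1, 2), zero_params, lambda = 1)
  expect_equal(lv$loss, 0)

  # single masked unit residual at lambda 0: loss 1
  lv <- compute_loss(matrix(0, 1, 1), matrix(1, 1, 1), matrix(1, 1, 1),
                     matrix(0, 1, 1), zero_params, lambda = 0)
  expect_equal(lv$loss, 1)
  expect_equal(lv$error, 1)

  # residuals 1 and 0 over two masked entries: mean 0.5
  lv <- compute_loss(matrix(c(0, 0), 1, 2), matrix(c(1, 0), 1, 2),
                     matrix(c(1, 1), 1, 2), matrix(0, 1, 2),
                     zero_params, lambda = 0)
  expect_equal(lv$loss, 0.5)

  # regularisation term adds lambda/2 * sum of squares
  params <- list(W_e = matrix(2, 1, 1), B_e = 1, W_d = matrix(1, 1, 1))
  lv <- compute_loss(matrix(1, 1, 1), matrix(1, 1, 1), matrix(1, 1, 1),
                     matrix(0, 1, 1), params, lambda = 2)
  expect_equal(lv$loss, 2 * 0.5 * (4 + 1 + 1))

  expect_error(compute_loss(matrix(0, 1, 1), matrix(0, 1, 1), matrix(0, 1, 1),
                            matrix(0, 1, 1), zero_params, 1), "empty")
})

test_that("training reduces the loss and is reproducible by seed", {
  ds <- tiny_dataset(seed = 3)
  m1 <- gcae_train(ds, n_latent = 4, epochs = 80, seed = 9)
  m2 <- gcae_train(ds, n_latent = 4, epochs = 80, seed = 9)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_lt(tail(m1$loss_history, 1), m1$loss_history[1])
  expect_equal(length(m1$loss_history), 80)
  expect_true(all(m1$embeddings$E >= 0))
  expect_true(all(is.finite(m1$error_history)))
})

test_that("training loss is invariant under consistent node permutation", {
  ds <- tiny_dataset(seed = 13)
  n_l <- nrow(ds$interactions$M); n_m <- ncol(ds$interactions$M)
  perm_l <- sample(n_l); perm_m <- sample(n_m)
  ds_perm <- structure(list(
    interactions = interaction_set(ds$interactions$M[perm_l, perm_m],
                                   ds$interactions$lnc_ids[perm_l],
                                   ds$interactions$mir_ids[perm_m]),
    lnc_features = feature_table(ds$lnc_features$F[perm_l, , drop = FALSE],
                                 ds$lnc_features$ids[perm_l]),
    mir_features = feature_table(ds$mir_features$F[perm_m, , drop = FALSE],
                                 ds$mir_features$ids[perm_m])
  ), class = "lm_dataset")
  # same params, same fixed masks (permuted consistently): identical loss
  G <- build_graph_inputs(ds)
  G_p <- build_graph_inputs(ds_perm)
  params <- init_params(ncol(G), 4, seed = 2)
  omega_p <- (ds$interactions$M == 1) * 1
  set.seed(4)
  omega_n <- sample_negatives(ds$interactions$M, 1)
  enc <- encode(G, params, n_l)
  lv <- compute_loss(decode(enc$E_l, enc$E_m, params$W_d),
                     ds$interactions$M, omega_p, omega_n, params, 0.5)
  enc_p <- encode(G_p, params, n_l)
  lv_p <- compute_loss(decode(enc_p$E_l, enc_p$E_m, params$W_d),
                       ds_perm$interactions$M,
                       omega_p[perm_l, perm_m], omega_n[perm_l, perm_m],
                       params, 0.5)
  expect_equal(lv_p$loss, lv$loss, tolerance = 1e-12)
})

test_that("stronger regularisation shrinks the trained encoder weights", {
  ds <- tiny_dataset(seed = 8)
  norms <- sapply(c(0.1, 1, 10), function(lam) {
    m <- gcae_train(ds, n_latent = 3, lambda = lam, epochs = 150, seed = 4)
    sqrt(sum(m$params$W_e^2))
  })
  expect_true(all(diff(norms) < 0))
})

test_that("prediction recomputes scores from the training graph", {
  ds <- tiny_dataset(seed = 6)
  m <- gcae_train(ds, n_latent = 4, epochs = 40, seed = 2)
  s <- predict_scores(m)
  expect_equal(dim(s), dim(ds$interactions$M))
  expect_true(all(is.finite(s)))
  # zero-weight model scores everything zero
  m0 <- m
  m0$params$W_e[] <- 0; m0$params$B_e[] <- 0; m0$params$W_d[] <- 0
  expect_equal(predict_scores(m0), matrix(0, nrow(s), ncol(s)),
               ignore_attr = TRUE)
  # S3 predict is the same path
  expect_equal(predict(m), s)
})
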