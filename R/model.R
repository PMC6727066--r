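#' Initialise encoder/decoder parameters
#'
#' Draws the encoder weights `W_e` (`D_total x n_latent`) and the bilinear
#' decoder weights `W_d` (`n_latent x n_latent`) from a zero-mean normal
#' with variance-scaled standard deviation `sqrt(2 / (fan_in + fan_out))`;
#' the encoder bias `B_e` (one row, broadcast across nodes) starts at zero.
#'
#' @param D_total total feature dimension (`D_l + D_m`).
#' @param n_latent latent dimension of the embedding space.
#' @param seed RNG seed; identical seeds give bit-identical draws.
#' @return a list with `W_e`, `B_e`, `W_d`, `n_latent`.
#' @export
init_params <- function(D_total, n_latent, seed = 1L) {
  stopifnot(D_total >= 1, n_latent >= 1)
  set.seed(seed)
  list(
    W_e = matrix(stats::rnorm(D_total * n_latent,
                              sd = sqrt(2 / (D_total + n_latent))),
                 D_total, n_latent),
    B_e = numeric(n_latent),
    W_d = matrix(stats::rnorm(n_latent * n_latent,
                              sd = sqrt(2 / (2 * n_latent))),
                 n_latent, n_latent),
    n_latent = as.integer(n_latent)
  )
}

#' Encode convolved features into latent embeddings
#'
#' `E = ReLU(G W_e + B_e)`, split into the lncRNA block `E_l` (first
#' `n_lnc` rows) and the miRNA block `E_m` (remaining rows). Embeddings are
#' elementwise nonnegative by construction.
#'
#' @param G convolved feature matrix.
#' @param params parameter list from [init_params()].
#' @param n_lnc number of lncRNA nodes (size of the leading row block).
#' @return a list with `E`, `E_l`, `E_m` and the pre-activation `Z`.
#' @export
encode <- function(G, params, n_lnc) {
  if (ncol(G) != nrow(params$W_e)) {
    stop("feature dimension ", ncol(G), " does not match encoder weights (",
         nrow(params$W_e), ")")
  }
  Z <- G %*% params$W_e
  Z <- Z + rep(params$B_e, each = nrow(Z))
  E <- pmax(Z, 0)
  list(E = E,
       E_l = E[seq_len(n_lnc), , drop = FALSE],
       E_m = E[-seq_len(n_lnc), , drop = FALSE],
       Z = Z)
}

#' Bilinear decoder
#'
#' Reconstructs the interaction score matrix `M' = E_l W_d E_m'` from the
#' two embedding blocks; the result has the shape of the input interaction
#' matrix and scores every lncRNA-miRNA pair, known or unlabeled.
#'
#' @param E_l,E_m embedding blocks for lncRNAs and miRNAs.
#' @param W_d `n_latent x n_latent` decoder weight matrix.
#' @return the `N_l x N_m` score matrix.
#' @export
decode <- function(E_l, E_m, W_d) {
  if (ncol(E_l) != nrow(W_d) || ncol(E_m) != ncol(W_d)) {
    stop("embedding dimension does not match decoder weights")
  }
  E_l %*% W_d %*% t(E_m)
}

#' Sample negative training pairs
#'
#' Draws a uniform sample, without replacement, of `round(p * n_pos)` zero
#' entries of the training interaction matrix to act as this epoch's
#' negatives, where `n_pos` is the number of training positives. If fewer
#' zeros exist the sample is capped with a warning. Uses the current RNG
#' state; seed it upstream for reproducibility.
#'
#' @param M_train binary training interaction matrix.
#' @param p negative-to-positive ratio (`p = 0` gives an empty mask).
#' @return a binary mask matrix, disjoint from the positives of `M_train`.
#' @export
sample_negatives <- function(M_train, p) {
  stopifnot(p >= 0)
  omega_n <- matrix(0, nrow(M_train), ncol(M_train))
  n_want <- round(p * sum(M_train))
  if (n_want == 0) return(omega_n)
  zeros <- which(M_train == 0)
  if (n_want > length(zeros)) {
    warning("requested ", n_want, " negatives but only ", length(zeros),
            " unlabeled pairs exist; capping")
    n_want <- length(zeros)
  }
  omega_n[sample(zeros, n_want)] <- 1
  omega_n
}

#' Masked training loss
#'
#' The objective is the mean squared reconstruction error over the masked
#' entries (training positives plus this epoch's sampled negatives) plus an
#' L2 penalty on all trainable parameters:
#' `loss = error + lambda * (||W_e||^2 + ||W_d||^2 + ||B_e||^2) / 2`
#' with Frobenius norms. The unpenalised first term is reported separately
#' as the training error.
#'
#' @param M_pred predicted score matrix.
#' @param M_train binary training interaction matrix.
#' @param omega_p,omega_n disjoint binary masks of positives and sampled
#'   negatives.
#' @param params parameter list (for the penalty term).
#' @param lambda penalty multiplier.
#' @return a list with `loss` and `error`.
#' @export
compute_loss <- function(M_pred, M_train, omega_p, omega_n, params,
                         lambda = 1) {
  n_mask <- sum(omega_p) + sum(omega_n)
  if (n_mask == 0) stop("empty training mask: no positives and no negatives")
  resid <- (M_pred - M_train) * (omega_p + omega_n)
  error <- sum(resid^2) / n_mask
  reg <- 0.5 * (sum(params$W_e^2) + sum(params$W_d^2) + sum(params$B_e^2))
  list(loss = error + lambda * reg, error = error)
}

# Forward pass + analytic gradients of the masked loss w.r.t. all three
# parameter blocks. The ReLU subgradient at 0 is taken as 0.
gcae_loss_grad <- function(G, params, M_train, omega_p, omega_n, lambda,
                           n_lnc) {
  enc <- encode(G, params, n_lnc)
  M_pred <- decode(enc$E_l, enc$E_m, params$W_d)
  lv <- compute_loss(M_pred, M_train, omega_p, omega_n, params, lambda)
  n_mask <- sum(omega_p) + sum(omega_n)
  R <- 2 * (M_pred - M_train) * (omega_p + omega_n) / n_mask
  gE_l <- R %*% enc$E_m %*% t(params$W_d)
  gE_m <- t(R) %*% enc$E_l %*% params$W_d
  gZ <- rbind(gE_l, gE_m) * (enc$Z > 0)
  list(
    loss = lv$loss, error = lv$error,
    gW_e = crossprod(G, gZ) + lambda * params$W_e,
    gB_e = colSums(gZ) + lambda * params$B_e,
    gW_d = crossprod(enc$E_l, R %*% enc$E_m) + lambda * params$W_d
  )
}

# Adaptive-moment gradient step (standard first/second-moment estimates
# with bias correction).
adam_init <- function(params) {
  list(m = lapply(params[c("W_e", "B_e", "W_d")], function(p) p * 0),
       v = lapply(params[c("W_e", "B_e", "W_d")], function(p) p * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in c("W_e", "B_e", "W_d")) {
    g <- grads[[paste0("g", nm)]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    m_hat <- state$m[[nm]] / (1 - beta1^state$t)
    v_hat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * m_hat / (sqrt(v_hat) + eps)
  }
  list(params = params, state = state)
}

#' Train the graph-convolutional auto-encoder
#'
#' Full-graph gradient training of the encoder/decoder on the masked
#' squared loss. Each epoch resamples the negative mask at ratio `p_ratio`
#' from the zeros of the training matrix, runs one adaptive-moment gradient
#' step over all parameters, and records the loss and the unpenalised
#' error. All randomness (initialisation, negative sampling) derives from
#' `seed`, so runs are reproducible.
#'
#' @param dataset an `lm_dataset`.
#' @param M_train optional binary training matrix replacing the dataset's
#'   full interaction matrix (cross-validation hides held-out folds here).
#' @param n_latent latent dimension of the embedding space.
#' @param lambda L2 penalty multiplier on the parameters.
#' @param p_ratio negative-to-positive sampling ratio per epoch.
#' @param epochs number of training epochs.
#' @param lr learning rate of the adaptive-moment optimiser.
#' @param seed master seed.
#' @param dialect graph filter dialect, see [normalize_adjacency()].
#' @param row_normalize L1-normalise feature rows before convolution.
#' @param verbose print the loss every 50 epochs.
#' @return an object of class `gcae_model` holding the trained parameters,
#'   final embeddings, loss/error histories, the training matrix and the
#'   configuration.
#' @export
gcae_train <- function(dataset, M_train = NULL, n_latent = 64L, lambda = 0.01,
                       p_ratio = 3, epochs = 600L, lr = 0.01, seed = 1L,
                       dialect = "renormalized", row_normalize = FALSE,
                       verbose = FALSE) {
  M <- if (is.null(M_train)) dataset$interactions$M else M_train
  stop_if_not_binary(M)
  n_lnc <- nrow(M)
  if (sum(M) == 0) stop("training matrix has no positive interactions")
  G <- build_graph_inputs(dataset, M, dialect = dialect,
                          row_normalize = row_normalize)
  params <- init_params(ncol(G), n_latent, derive_seed(seed, "init"))
  omega_p <- (M == 1) * 1
  if (round(p_ratio * sum(M)) > sum(M == 0)) {
    warning("requested ", round(p_ratio * sum(M)),
            " negatives per epoch but only ", sum(M == 0),
            " unlabeled pairs exist; capping")
  }
  state <- adam_init(params)
  loss_history <- error_history <- numeric(epochs)
  set.seed(derive_seed(seed, "negatives"))
  for (ep in seq_len(epochs)) {
    omega_n <- suppressWarnings(sample_negatives(M, p_ratio))
    gr <- gcae_loss_grad(G, params, M, omega_p, omega_n, lambda, n_lnc)
    if (!is.finite(gr$loss)) {
      stop("non-finite loss at epoch ", ep,
           "; try a smaller learning rate or latent dimension")
    }
    loss_history[ep] <- gr$loss
    error_history[ep] <- gr$error
    upd <- adam_step(params, gr, state, lr)
    params <- upd$params
    state <- upd$state
    if (verbose && ep %% 50 == 0) {
      message(sprintf("epoch %d: loss %.5f error %.5f", ep, gr$loss, gr$error))
    }
  }
  enc <- encode(G, params, n_lnc)
  structure(list(
    params = params,
    embeddings = list(E = enc$E, E_l = enc$E_l, E_m = enc$E_m),
    loss_history = loss_history,
    error_history = error_history,
    M_train = M,
    dataset = dataset,
    config = list(n_latent = n_latent, lambda = lambda, p_ratio = p_ratio,
                  epochs = epochs, lr = lr, seed = seed, dialect = dialect,
                  row_normalize = row_normalize)
  ), class = "gcae_model")
}

#' @export
print.gcae_model <- function(x, ...) {
  cat(sprintf(paste0("gcae_model: %d latent factors, %d epochs, ",
                     "final loss %.5f (error %.5f)\n"),
              x$params$n_latent, length(x$loss_history),
              utils::tail(x$loss_history, 1),
              utils::tail(x$error_history, 1)))
  invisible(x)
}

#' Score all lncRNA-miRNA pairs with a trained model
#'
#' Rebuilds the convolved features from the model's training adjacency and
#' the dataset's feature tables, encodes, and decodes, returning the full
#' `N_l x N_m` score matrix (including known positives; masking is the
#' evaluator's job).
#'
#' @param model a trained `gcae_model`.
#' @param dataset dataset to score; defaults to the training dataset.
#' @return numeric score matrix.
#' @export
predict_scores <- function(model, dataset = model$dataset) {
  if (!identical(dim(model$M_train), dim(dataset$interactions$M))) {
    stop("model and dataset shapes do not match")
  }
  G <- build_graph_inputs(dataset, model$M_train,
                          dialect = model$config$dialect,
                          row_normalize = model$config$row_normalize)
  enc <- encode(G, model$params, nrow(model$M_train))
  decode(enc$E_l, enc$E_m, model$params$W_d)
}

#' @export
predict.gcae_model <- function(object, dataset = object$dataset, ...) {
  predict_scores(object, dataset)
}
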