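#' Pearson similarity of expression profiles
#'
#' Pairwise Pearson correlation between node feature rows. Rows with zero
#' variance get similarity 0 to every other node and 1 to themselves, so
#' the matrix stays symmetric with a unit diagonal.
#'
#' @param features a `feature_table` or numeric matrix (nodes in rows,
#'   at least two feature columns).
#' @return symmetric similarity matrix with entries in `[-1, 1]`.
#' @export
pearson_similarity <- function(features) {
  F <- if (inherits(features, "feature_table")) features$F else features
  stop_if_not_matrix(F, "features")
  if (ncol(F) < 2) stop("Pearson similarity needs >= 2 feature columns")
  S <- suppressWarnings(stats::cor(t(F)))
  S[!is.finite(S)] <- 0
  diag(S) <- 1
  S
}

#' Neighborhood collaborative-filtering scores
#'
#' Similarity-weighted vote over the interactions of a node's neighbors:
#' for axis `"lnc"`,
#' `score(i, j) = sum_{i' != i} sim(i, i') M(i', j) / sum_{i' != i} |sim(i, i')|`
#' (0 when the denominator vanishes); axis `"mir"` is the symmetric formula
#' over columns. Negative similarities are kept and the denominator uses
#' absolute values, so anticorrelated neighbors vote against a link.
#'
#' @param M binary interaction matrix.
#' @param sim similarity matrix for the chosen axis (`N_l x N_l` for
#'   `"lnc"`, `N_m x N_m` for `"mir"`).
#' @param axis which node type supplies the neighborhood.
#' @return score matrix with the shape of `M`.
#' @export
neighbor_cf_scores <- function(M, sim, axis = c("lnc", "mir")) {
  axis <- match.arg(axis)
  stop_if_not_binary(M)
  n <- if (axis == "lnc") nrow(M) else ncol(M)
  if (!identical(dim(sim), c(n, n))) {
    stop("similarity matrix has the wrong shape for axis '", axis, "'")
  }
  W <- sim
  diag(W) <- 0
  den <- rowSums(abs(W))
  den <- ifelse(den > 0, den, Inf)  # -> score 0 for isolated rows
  if (axis == "lnc") {
    (W %*% M) / den
  } else {
    sweep(M %*% W, 2, den, "/")
  }
}

#' Truncated-SVD reconstruction scores
#'
#' Rank-`rank` singular-value reconstruction of the interaction matrix:
#' the score of a pair is its entry in the best rank-`rank` least-squares
#' approximation of `M`.
#'
#' @param M binary interaction matrix.
#' @param rank truncation rank, between 1 and `min(dim(M))`.
#' @return score matrix with the shape of `M`.
#' @export
svd_cf_scores <- function(M, rank) {
  stop_if_not_binary(M)
  if (rank < 1 || rank > min(dim(M))) {
    stop("rank must lie in [1, ", min(dim(M)), "]")
  }
  sv <- svd(M)
  idx <- seq_len(rank)
  sv$u[, idx, drop = FALSE] %*%
    (sv$d[idx] * t(sv$v[, idx, drop = FALSE]))
}

#' Katz-index scores on the bipartite graph
#'
#' Katz connectivity index on the block adjacency of the bipartite graph:
#' either the closed form `(I - beta A)^{-1} - I` (requires
#' `beta < 1 / rho(A)` for convergence of the underlying series) or the
#' truncated power series `sum_{k=1..k_max} beta^k A^k`. Only walks of odd
#' length connect the two node types, and the lncRNA-by-miRNA block of the
#' result is returned as the score matrix.
#'
#' @param M binary interaction matrix.
#' @param beta walk attenuation factor (> 0).
#' @param k_max `"closed_form"` (default) or an integer truncation order.
#' @return score matrix with the shape of `M`.
#' @export
katz_scores <- function(M, beta = 0.01, k_max = "closed_form") {
  stop_if_not_binary(M)
  stopifnot(beta > 0)
  A <- assemble_adjacency_block(M)
  n <- nrow(A)
  if (identical(k_max, "closed_form")) {
    rho <- max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
    if (rho > 0 && beta >= 1 / rho) {
      stop("beta = ", beta, " >= 1/spectral radius = ", format(1 / rho),
           "; the Katz series diverges")
    }
    K <- solve(diag(n) - beta * A) - diag(n)
  } else {
    k_max <- as.integer(k_max)
    stopifnot(k_max >= 1)
    K <- matrix(0, n, n)
    Ak <- diag(n)
    for (k in seq_len(k_max)) {
      Ak <- Ak %*% (beta * A)
      K <- K + Ak
    }
  }
  K[seq_len(nrow(M)), nrow(M) + seq_len(ncol(M)), drop = FALSE]
}

#' Latent factor model scores
#'
#' Plain matrix factorisation `M ~ P Q'` fitted by momentum gradient
#' descent on the same masked squared loss used by the auto-encoder
#' (training positives plus negatives resampled each epoch at ratio `p`)
#' with optional L2 regularisation on both factors. Momentum descent is
#' used deliberately: per-coordinate adaptive optimisers fit the masked
#' entries quickly but lose the implicit low-norm bias that makes gradient
#' matrix completion generalise to unobserved pairs.
#'
#' @param M binary interaction matrix.
#' @param rank number of latent factors.
#' @param lambda_reg L2 penalty multiplier on `P` and `Q`.
#' @param p negative-to-positive sampling ratio per epoch.
#' @param epochs training epochs.
#' @param lr learning rate; steps use the masked-sum gradient, whose
#'   per-entry scale does not depend on the problem size, so one rate
#'   works from toy matrices up to the full benchmark.
#' @param seed master seed (initialisation and negative sampling).
#' @param momentum heavy-ball momentum coefficient.
#' @return score matrix `P %*% t(Q)`.
#' @export
latent_factor_scores <- function(M, rank = 8L, lambda_reg = 0, p = 3,
                                 epochs = 600L, lr = 0.005, seed = 1L,
                                 momentum = 0.9) {
  stop_if_not_binary(M)
  stopifnot(rank >= 1)
  n_l <- nrow(M); n_m <- ncol(M)
  set.seed(derive_seed(seed, "init"))
  P <- matrix(stats::rnorm(n_l * rank, sd = 0.1), n_l, rank)
  Q <- matrix(stats::rnorm(n_m * rank, sd = 0.1), n_m, rank)
  omega_p <- (M == 1) * 1
  n_zero <- sum(M == 0)
  if (round(p * sum(M)) > n_zero) {
    warning("requested ", round(p * sum(M)), " negatives per epoch but only ",
            n_zero, " unlabeled pairs exist; capping")
  }
  uP <- P * 0
  uQ <- Q * 0
  set.seed(derive_seed(seed, "negatives"))
  for (t in seq_len(epochs)) {
    omega_n <- suppressWarnings(sample_negatives(M, p))
    R <- 2 * (P %*% t(Q) - M) * (omega_p + omega_n)
    if (!all(is.finite(R))) stop("non-finite loss at epoch ", t)
    uP <- momentum * uP - lr * (R %*% Q + lambda_reg * P)
    uQ <- momentum * uQ - lr * (t(R) %*% P + lambda_reg * Q)
    P <- P + uP
    Q <- Q + uQ
  }
  P %*% t(Q)
}
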