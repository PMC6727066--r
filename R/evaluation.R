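#' Random k-fold partition of the positive edges
#'
#' Assigns each known interaction to one of `k` folds uniformly at random;
#' fold sizes differ by at most one. Reproducible by seed.
#'
#' @param n_edges number of positive edges to partition.
#' @param k fold count (>= 2).
#' @param seed RNG seed.
#' @return an object of class `fold_plan` with `k`, `assignments`, `seed`.
#' @export
kfold_split <- function(n_edges, k, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  if (k > n_edges) stop("k = ", k, " exceeds the number of edges (", n_edges, ")")
  set.seed(seed)
  structure(list(k = as.integer(k),
                 assignments = sample(rep(seq_len(k), length.out = n_edges)),
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Rank prediction scores over the candidate set
#'
#' The candidate set is every pair that is not a training positive, i.e.
#' all unlabeled pairs plus any held-out test positives. Ranks are
#' assigned by descending score; ties receive the average of the ranks
#' they span, so rank 1 is the top candidate.
#'
#' @param scores numeric score matrix.
#' @param train_positive_mask logical/binary matrix of training positives
#'   (same shape as `scores`).
#' @return a list with the candidate `index` (into the matrix) and `rank`.
#' @export
rank_candidates <- function(scores, train_positive_mask) {
  if (!identical(dim(scores), dim(train_positive_mask))) {
    stop("score and mask shapes differ")
  }
  cand <- which(train_positive_mask == 0)
  if (length(cand) == 0) stop("empty candidate set: every pair is a training positive")
  list(index = cand,
       rank = rank(-scores[cand], ties.method = "average"))
}

#' ROC curve and AUC over a candidate set
#'
#' The AUC is the Mann-Whitney statistic: the fraction of
#' (positive, negative) candidate pairs in which the positive scores
#' higher, counting exact ties as 1/2 — computed from average ranks so it
#' is exact under ties. The ROC curve sweeps the score threshold through
#' the tied groups, starting at (0, 0) and ending at (1, 1); its
#' trapezoidal integral equals the rank-based AUC.
#'
#' @param scores numeric vector of candidate scores.
#' @param labels binary vector: 1 for held-out true interactions, 0 for
#'   unlabeled candidates.
#' @param curve also return the ROC points (set `FALSE` to save memory in
#'   tight loops).
#' @return a list with `auc`, `n_pos`, `n_neg`, and (if requested) `roc`, a
#'   data.frame of `fpr`/`tpr` points.
#' @export
roc_auc <- function(scores, labels, curve = TRUE) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC needs at least one positive and one negative candidate")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  out <- list(auc = auc, n_pos = n_pos, n_neg = n_neg)
  if (curve) {
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]
    f <- labels[ord]
    last <- c(which(diff(s) != 0), length(s))  # end of each tied block
    out$roc <- data.frame(
      fpr = c(0, cumsum(1 - f)[last] / n_neg),
      tpr = c(0, cumsum(f)[last] / n_pos)
    )
  }
  out
}

#' Repeated k-fold cross-validation of a link-prediction method
#'
#' For each repeat and each fold, the fold's positive edges are hidden
#' (set to 0 in the training matrix), the method scores every pair from
#' the training matrix alone, and the held-out edges are ranked among all
#' candidates (every pair that is not a training positive). The AUC of
#' that ranking is recorded per fold; the summary reports the mean over
#' all folds/repeats and the standard deviation of the per-repeat means.
#' Feature tables are never modified — only the interaction matrix is
#' masked. Each repeat derives its own fold seed from the master seed, so
#' any single repeat can be reproduced in isolation.
#'
#' @param method a scoring function `function(M_train, dataset)` returning
#'   an `N_l x N_m` score matrix; see [method_gcae()] and friends.
#' @param dataset an `lm_dataset`.
#' @param k fold count.
#' @param repeats number of independent repetitions of the fold split.
#' @param seed master seed.
#' @param pool_roc accumulate candidate scores across folds for a pooled
#'   ROC curve (costs memory on large problems).
#' @return an object of class `cv_result`: matrix `auc`
#'   (`repeats x k`), `mean_auc`, `sd_auc`, and optionally `roc`.
#' @export
cross_validate <- function(method, dataset, k = 5L, repeats = 20L, seed = 1L,
                           pool_roc = FALSE) {
  M <- dataset$interactions$M
  pos <- which(M == 1)
  aucs <- matrix(NA_real_, repeats, k)
  pool_s <- pool_f <- if (pool_roc) vector("list", repeats * k)
  for (r in seq_len(repeats)) {
    plan <- kfold_split(length(pos), k, derive_seed(seed, "folds") + r - 1L)
    for (f in seq_len(k)) {
      M_train <- M
      M_train[pos[plan$assignments == f]] <- 0
      scores <- method(M_train, dataset)
      cand <- which(M_train == 0)
      flags <- as.numeric(M[cand] == 1)
      aucs[r, f] <- roc_auc(scores[cand], flags, curve = FALSE)$auc
      if (pool_roc) {
        pool_s[[(r - 1) * k + f]] <- scores[cand]
        pool_f[[(r - 1) * k + f]] <- flags
      }
    }
  }
  per_repeat <- rowMeans(aucs)
  out <- list(auc = aucs,
              mean_auc = mean(per_repeat),
              sd_auc = if (repeats > 1) stats::sd(per_repeat) else NA_real_,
              k = k, repeats = repeats, seed = seed)
  if (pool_roc) {
    out$roc <- roc_auc(unlist(pool_s), unlist(pool_f))$roc
  }
  structure(out, class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d-fold CV, %d repeat(s): mean AUC %.4f (sd %.4f)\n",
              x$k, x$repeats, x$mean_auc, x$sd_auc))
  invisible(x)
}

# method factories -------------------------------------------------------

#' Scoring-method factories for cross-validation
#'
#' Each factory returns a `function(M_train, dataset)` producing an
#' `N_l x N_m` score matrix, suitable for [cross_validate()]:
#'
#' * `method_gcae()`: the graph-convolutional auto-encoder, trained fresh
#'   on each training matrix.
#' * `method_neighbor_cf()`: neighborhood collaborative filtering on the
#'   Pearson similarity of the chosen side's expression profiles.
#' * `method_svd()`: truncated-SVD reconstruction of the training matrix.
#' * `method_katz()`: Katz index on the bipartite block graph.
#' * `method_lfm()`: the basic latent factor model.
#' * `method_random()`: scores i.i.d. uniform noise — a chance-level
#'   control whose AUC should sit near 0.5.
#' * `method_oracle()`: returns the dataset's full interaction matrix,
#'   test edges included; a deliberate-leakage control whose AUC is 1.
#'
#' @param n_latent,lambda,p_ratio,epochs,lr,seed,dialect,row_normalize
#'   passed to [gcae_train()].
#' @param axis,rank,beta,k_max,lambda_reg baseline-specific knobs, see
#'   [neighbor_cf_scores()], [svd_cf_scores()], [katz_scores()],
#'   [latent_factor_scores()].
#' @return a scoring function.
#' @name method_factories
NULL

#' @rdname method_factories
#' @export
method_gcae <- function(n_latent = 64L, lambda = 0.01, p_ratio = 3,
                        epochs = 600L, lr = 0.01, seed = 1L,
                        dialect = "renormalized", row_normalize = FALSE) {
  function(M_train, dataset) {
    model <- gcae_train(dataset, M_train = M_train, n_latent = n_latent,
                        lambda = lambda, p_ratio = p_ratio, epochs = epochs,
                        lr = lr, seed = seed, dialect = dialect,
                        row_normalize = row_normalize)
    predict_scores(model, dataset)
  }
}

#' @rdname method_factories
#' @export
method_neighbor_cf <- function(axis = c("lnc", "mir")) {
  axis <- match.arg(axis)
  function(M_train, dataset) {
    feats <- if (axis == "lnc") dataset$lnc_features else dataset$mir_features
    neighbor_cf_scores(M_train, pearson_similarity(feats), axis)
  }
}

#' @rdname method_factories
#' @export
method_svd <- function(rank = 6L) {
  function(M_train, dataset) svd_cf_scores(M_train, rank)
}

#' @rdname method_factories
#' @export
method_katz <- function(beta = 0.01, k_max = "closed_form") {
  function(M_train, dataset) katz_scores(M_train, beta, k_max)
}

#' @rdname method_factories
#' @export
method_lfm <- function(rank = 8L, lambda_reg = 0, p = 3, epochs = 600L,
                       lr = 0.005, seed = 1L) {
  function(M_train, dataset) {
    latent_factor_scores(M_train, rank, lambda_reg, p, epochs, lr, seed)
  }
}

#' @rdname method_factories
#' @export
method_random <- function(seed = 1L) {
  counter <- 0L
  function(M_train, dataset) {
    counter <<- counter + 1L
    set.seed(derive_seed(seed, "scores") + counter)
    matrix(stats::runif(length(M_train)), nrow(M_train), ncol(M_train))
  }
}

#' @rdname method_factories
#' @export
method_oracle <- function() {
  function(M_train, dataset) dataset$interactions$M
}
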