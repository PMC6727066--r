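#' Block-diagonal feature matrix
#'
#' Stacks the lncRNA and miRNA feature matrices into one
#' `(N_l + N_m) x (D_l + D_m)` matrix with `F_l` in the top-left block,
#' `F_m` in the bottom-right block and zeros elsewhere, so both node types
#' live in a single feature space.
#'
#' @param F_l,F_m numeric feature matrices for the two node types.
#' @return the block-diagonal matrix `X`.
#' @export
assemble_feature_block <- function(F_l, F_m) {
  stop_if_not_matrix(F_l, "F_l")
  stop_if_not_matrix(F_m, "F_m")
  X <- matrix(0, nrow(F_l) + nrow(F_m), ncol(F_l) + ncol(F_m))
  X[seq_len(nrow(F_l)), seq_len(ncol(F_l))] <- F_l
  X[nrow(F_l) + seq_len(nrow(F_m)), ncol(F_l) + seq_len(ncol(F_m))] <- F_m
  X
}

#' Block adjacency of the bipartite graph
#'
#' Expands the `N_l x N_m` interaction matrix into the symmetric
#' `(N_l + N_m) x (N_l + N_m)` adjacency `A = [[0, M], [M', 0]]` of the
#' undirected bipartite graph; within-type blocks and the diagonal are zero.
#'
#' @param M binary interaction matrix.
#' @return the symmetric block adjacency matrix.
#' @export
assemble_adjacency_block <- function(M) {
  stop_if_not_binary(M)
  n_l <- nrow(M); n_m <- ncol(M)
  A <- matrix(0, n_l + n_m, n_l + n_m)
  A[seq_len(n_l), n_l + seq_len(n_m)] <- M
  A[n_l + seq_len(n_m), seq_len(n_l)] <- t(M)
  A
}

#' Normalized graph filter
#'
#' Builds the one-hop spectral convolution filter from a symmetric
#' adjacency matrix. Two dialects are provided:
#'
#' * `"renormalized"` (default): self-loops are added before degree
#'   normalisation, `S = D~^{-1/2} (A + I) D~^{-1/2}` with
#'   `D~_ii = sum_j (A + I)_ij`. Eigenvalues lie in `[-1, 1]`, which keeps
#'   repeated application numerically stable.
#' * `"plain"`: `S = I + D^{-1/2} A D^{-1/2}` with the convention
#'   `D_ii^{-1/2} = 0` for isolated nodes.
#'
#' Both coincide with the identity filter on an edgeless graph.
#'
#' @param A symmetric nonnegative adjacency matrix.
#' @param dialect `"renormalized"` or `"plain"`.
#' @return the symmetric filter matrix `S`.
#' @export
normalize_adjacency <- function(A, dialect = c("renormalized", "plain")) {
  dialect <- match.arg(dialect)
  stop_if_not_matrix(A, "A")
  if (nrow(A) != ncol(A)) stop("`A` must be square")
  if (max(abs(A - t(A))) > 0) stop("`A` must be symmetric")
  if (any(A < 0)) stop("`A` must be nonnegative")
  n <- nrow(A)
  if (dialect == "renormalized") {
    At <- A + diag(n)
    dinv <- 1 / sqrt(rowSums(At))  # degrees >= 1 because of the self-loop
    dinv * At * rep(dinv, each = n)
  } else {
    deg <- rowSums(A)
    dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
    diag(n) + dinv * A * rep(dinv, each = n)
  }
}

#' Apply a graph filter to node features
#'
#' Computes `G = S %*% X`: row `i` of the result mixes the features of node
#' `i`'s (weighted) neighborhood, replacing each raw feature vector with a
#' degree-normalised neighborhood average.
#'
#' @param S `n x n` filter matrix.
#' @param X `n x d` node feature matrix.
#' @return the convolved `n x d` feature matrix.
#' @export
graph_convolve <- function(S, X) {
  stop_if_not_matrix(S, "S")
  stop_if_not_matrix(X, "X")
  if (ncol(S) != nrow(X)) {
    stop("filter has ", ncol(S), " columns but feature matrix has ",
         nrow(X), " rows")
  }
  S %*% X
}

# L1 row normalisation of a feature matrix; all-zero rows pass through.
row_normalize_l1 <- function(X) {
  s <- rowSums(abs(X))
  X / ifelse(s > 0, s, 1)
}

#' Convolved features for a dataset
#'
#' Convenience wrapper assembling the block feature matrix and block
#' adjacency for a dataset (optionally with a fold-masked training matrix)
#' and applying the normalized graph filter.
#'
#' @param dataset an `lm_dataset`.
#' @param M_train optional training interaction matrix overriding the
#'   dataset's full matrix (used during cross-validation).
#' @param dialect filter dialect, see [normalize_adjacency()].
#' @param row_normalize L1-normalise feature rows before convolution.
#' @return the convolved `(N_l + N_m) x (D_l + D_m)` matrix `G`.
#' @export
build_graph_inputs <- function(dataset, M_train = NULL,
                               dialect = "renormalized",
                               row_normalize = FALSE) {
  M <- if (is.null(M_train)) dataset$interactions$M else M_train
  stop_if_not_binary(M)
  if (!identical(dim(M), dim(dataset$interactions$M))) {
    stop("`M_train` shape does not match the dataset")
  }
  X <- assemble_feature_block(dataset$lnc_features$F, dataset$mir_features$F)
  if (row_normalize) X <- row_normalize_l1(X)
  S <- normalize_adjacency(assemble_adjacency_block(M), dialect)
  graph_convolve(S, X)
}
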