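# Small in-code fixtures shared across test files.

# A tiny but non-degenerate aligned dataset (deterministic).
tiny_dataset <- function(n_l = 6, n_m = 5, d_l = 3, d_m = 4, seed = 42) {
  set.seed(seed)
  M <- matrix(rbinom(n_l * n_m, 1, 0.3), n_l, n_m)
  M[1, 1] <- 1  # guarantee at least one edge
  ds <- structure(list(
    interactions = interaction_set(M, sprintf("L%d", seq_len(n_l)),
                                   sprintf("m%d", seq_len(n_m))),
    lnc_features = feature_table(matrix(abs(rnorm(n_l * d_l)), n_l, d_l),
                                 sprintf("L%d", seq_len(n_l))),
    mir_features = feature_table(matrix(abs(rnorm(n_m * d_m)), n_m, d_m),
                                 sprintf("m%d", seq_len(n_m)))
  ), class = "lm_dataset")
  ds
}

# Write an edge list to a temp file, return the path.
write_edges_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Write a feature TSV (header + id column) to a temp file.
write_features_tmp <- function(ids, F) {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(id = ids, F, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Brute-force Mann-Whitney AUC: loop over all (positive, negative) pairs,
# ties count one half. Independent of the rank-based implementation.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

# Trapezoidal integral of an ROC curve data.frame.
trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}
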