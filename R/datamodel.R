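#' Bipartite interaction set
#'
#' Container for a binary lncRNA-miRNA interaction matrix together with the
#' identifier lists of both node types. Entry `M[i, j] == 1` records an
#' experimentally confirmed interaction between lncRNA `lnc_ids[i]` and
#' miRNA `mir_ids[j]`; `0` means the pair is unlabeled (not known to
#' interact, but not confirmed negative either).
#'
#' @param M binary numeric matrix, lncRNAs in rows, miRNAs in columns.
#' @param lnc_ids,mir_ids character vectors of unique identifiers matching
#'   the row/column counts of `M`.
#' @return an object of class `interaction_set`.
#' @export
interaction_set <- function(M, lnc_ids, mir_ids) {
  stop_if_not_binary(M)
  lnc_ids <- as.character(lnc_ids)
  mir_ids <- as.character(mir_ids)
  if (nrow(M) != length(lnc_ids) || ncol(M) != length(mir_ids)) {
    stop("dimensions of `M` do not match the identifier lists")
  }
  if (anyDuplicated(lnc_ids) || anyDuplicated(mir_ids)) {
    stop("node identifiers must be unique within each side")
  }
  dimnames(M) <- list(lnc_ids, mir_ids)
  structure(list(lnc_ids = lnc_ids, mir_ids = mir_ids, M = M),
            class = "interaction_set")
}

#' @export
print.interaction_set <- function(x, ...) {
  cat(sprintf("interaction_set: %d lncRNAs x %d miRNAs, %d known interactions\n",
              nrow(x$M), ncol(x$M), sum(x$M)))
  invisible(x)
}

#' Per-node feature table
#'
#' Numeric feature rows (one per node), typically expression levels across
#' tissues or cell lines. Values are used raw by downstream code unless an
#' explicit normalisation flag is set.
#'
#' @param F numeric matrix, one row per node.
#' @param ids character vector of unique node identifiers, length `nrow(F)`.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(F, ids) {
  stop_if_not_matrix(F, "F")
  if (ncol(F) < 1) stop("feature table needs at least one column")
  ids <- as.character(ids)
  if (nrow(F) != length(ids)) stop("row count does not match identifier list")
  if (anyDuplicated(ids)) stop("duplicated node identifier: ",
                               ids[duplicated(ids)][1])
  rownames(F) <- ids
  structure(list(ids = ids, F = F), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d nodes x %d features\n",
              nrow(x$F), ncol(x$F)))
  invisible(x)
}

#' Read an interaction edge list
#'
#' Parses a headerless two-column tab-separated file of
#' `(lncRNA_id, miRNA_id)` pairs into an [interaction_set()]. Duplicate
#' lines collapse to a single interaction; node order is first-appearance
#' order in the file.
#'
#' @param path path to the TSV file.
#' @return an `interaction_set`.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no edges in file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, function(p) {
    length(p) != 2 || any(!nzchar(trimws(p)))
  }, logical(1)))
  if (length(bad)) {
    stop("malformed interaction line ", bad[1], " in ", path,
         ": expected two non-empty tab-separated fields")
  }
  lnc <- trimws(vapply(parts, `[`, character(1), 1))
  mir <- trimws(vapply(parts, `[`, character(1), 2))
  lnc_ids <- unique(lnc)
  mir_ids <- unique(mir)
  M <- matrix(0, length(lnc_ids), length(mir_ids))
  M[cbind(match(lnc, lnc_ids), match(mir, mir_ids))] <- 1
  interaction_set(M, lnc_ids, mir_ids)
}

#' Write an interaction set as an edge list
#'
#' Inverse of [read_interactions()]: one tab-separated `lncRNA_id miRNA_id`
#' line per known interaction, in row-major order.
#'
#' @param x an `interaction_set`.
#' @param path output path.
#' @export
write_interactions <- function(x, path) {
  idx <- which(t(x$M) == 1)  # transpose so edges come out row-major
  j <- (idx - 1) %% ncol(x$M) + 1
  i <- (idx - 1) %/% ncol(x$M) + 1
  writeLines(paste(x$lnc_ids[i], x$mir_ids[j], sep = "\t"), path)
  invisible(path)
}

#' Read a feature table
#'
#' Expects a tab-separated file with a header line; the first column holds
#' node identifiers, every remaining column a numeric feature.
#'
#' @param path path to the TSV file.
#' @return a `feature_table`.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("feature file needs an id column plus >= 1 feature")
  ids <- trimws(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  F <- suppressWarnings(apply(vals, 2, as.numeric))
  if (!is.matrix(F)) F <- matrix(F, nrow = nrow(df))
  if (anyNA(F)) {
    bad <- which(is.na(F), arr.ind = TRUE)[1, ]
    stop("non-numeric value at data row ", bad[1], ", feature column ",
         bad[2], " of ", path)
  }
  colnames(F) <- colnames(df)[-1]
  feature_table(F, ids)
}

#' Write a feature table
#' @param x a `feature_table`.
#' @param path output path.
#' @export
write_features <- function(x, path) {
  df <- data.frame(id = x$ids, x$F, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align interactions with feature tables
#'
#' Keeps only nodes that occur both in the interaction set and in the
#' corresponding feature table (exact string match after whitespace
#' trimming); interactions involving unmatched nodes are dropped, and the
#' feature tables are reordered to the interaction node order. Counts of
#' kept/dropped nodes are reported via [message()].
#'
#' @param interactions an `interaction_set`.
#' @param lnc_features,mir_features `feature_table`s for the two sides.
#' @param quiet suppress the kept/dropped report.
#' @return an object of class `lm_dataset` with elements `interactions`,
#'   `lnc_features`, `mir_features`.
#' @export
align_dataset <- function(interactions, lnc_features, mir_features,
                          quiet = FALSE) {
  keep_l <- interactions$lnc_ids[interactions$lnc_ids %in% lnc_features$ids]
  keep_m <- interactions$mir_ids[interactions$mir_ids %in% mir_features$ids]
  if (length(keep_l) == 0) stop("no lncRNA id matches between interactions and features")
  if (length(keep_m) == 0) stop("no miRNA id matches between interactions and features")
  if (!quiet) {
    message(sprintf("aligned %d/%d lncRNAs and %d/%d miRNAs",
                    length(keep_l), length(interactions$lnc_ids),
                    length(keep_m), length(interactions$mir_ids)))
  }
  M <- interactions$M[match(keep_l, interactions$lnc_ids),
                      match(keep_m, interactions$mir_ids), drop = FALSE]
  structure(list(
    interactions = interaction_set(M, keep_l, keep_m),
    lnc_features = feature_table(
      lnc_features$F[match(keep_l, lnc_features$ids), , drop = FALSE], keep_l),
    mir_features = feature_table(
      mir_features$F[match(keep_m, mir_features$ids), , drop = FALSE], keep_m)
  ), class = "lm_dataset")
}

#' @export
print.lm_dataset <- function(x, ...) {
  cat(sprintf(paste0("lm_dataset: %d lncRNAs (%d features) x %d miRNAs ",
                     "(%d features), %d known interactions\n"),
              nrow(x$interactions$M), ncol(x$lnc_features$F),
              ncol(x$interactions$M), ncol(x$mir_features$F),
              sum(x$interactions$M)))
  invisible(x)
}

#' Write top-ranked candidate predictions
#'
#' Emits the unlabeled pairs (entries of `M` equal to 0) sorted by
#' descending score, truncated to `top_k`, as a four-column TSV with header
#' `lncRNA_id miRNA_id score rank`. Score ties are broken by
#' `(lncRNA_id, miRNA_id)` lexicographic order so output is reproducible.
#'
#' @param scores numeric score matrix with the shape of `M`.
#' @param dataset an `lm_dataset`.
#' @param path output path.
#' @param top_k maximum number of rows to write.
#' @return the output path, invisibly.
#' @export
write_predictions <- function(scores, dataset, path, top_k = 1000L) {
  M <- dataset$interactions$M
  if (!identical(dim(scores), dim(M))) {
    stop("score matrix shape does not match the interaction matrix")
  }
  cand <- which(M == 0, arr.ind = TRUE)
  df <- data.frame(
    lncRNA_id = dataset$interactions$lnc_ids[cand[, 1]],
    miRNA_id = dataset$interactions$mir_ids[cand[, 2]],
    score = scores[cand],
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$score, df$lncRNA_id, df$miRNA_id), , drop = FALSE]
  df <- utils::head(df, top_k)
  df$rank <- seq_len(nrow(df))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
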