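test_that("edge lists parse into the expected binary matrix", {
  x <- read_interactions(write_edges_tmp(c("L1\tm1", "L2\tm2")))
  expect_equal(unname(x$M), matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(x$lnc_ids, c("L1", "L2"))
  expect_equal(x$mir_ids, c("m1", "m2"))

  # duplicates collapse to a single edge
  y <- read_interactions(write_edges_tmp(c("L1\tm1", "L1\tm1")))
  expect_equal(unname(y$M), matrix(1, 1, 1))
  expect_equal(sum(y$M), 1)

  # surrounding whitespace is trimmed
  z <- read_interactions(write_edges_tmp(c(" L1 \tm1")))
  expect_equal(z$lnc_ids, "L1")
})

test_that("malformed or empty edge files raise informative errors", {
  expect_error(read_interactions(write_edges_tmp(c("L1\tm1", "only_one_field"))),
               "line 2")
  expect_error(read_interactions(write_edges_tmp(c("L1\tm1\textra"))), "line 1")
  expect_error(read_interactions(write_edges_tmp(character(0))), "no edges")
})

test_that("feature files parse with header, id column, numeric body", {
  x <- read_features(write_features_tmp(c("a", "b", "c"),
                                        matrix(runif(3 * 22), 3, 22)))
  expect_equal(ncol(x$F), 22)
  expect_equal(x$ids, c("a", "b", "c"))

  y <- read_features(write_features_tmp("solo", matrix(5.0, 1, 1)))
  expect_equal(unname(y$F), matrix(5.0, 1, 1))

  expect_error(read_features(write_features_tmp("a", matrix("oops", 1, 1))),
               "non-numeric")
  expect_error(
    read_features(write_edges_tmp(c("id\tf1", "a\t1", "a\t2"))),
    "duplicated|duplicate")
})

test_that("row order does not matter once features are aligned by id", {
  F <- matrix(rnorm(6), 3, 2)
  a <- read_features(write_features_tmp(c("x", "y", "z"), F))
  b <- read_features(write_features_tmp(c("z", "x", "y"), F[c(3, 1, 2), ]))
  ord_a <- order(a$ids); ord_b <- order(b$ids)
  expect_equal(a$F[ord_a, ], b$F[ord_b, ], ignore_attr = TRUE)
})

test_that("alignment keeps the id intersection and drops orphan edges", {
  ints <- interaction_set(matrix(c(1, 0, 1, 0, 1, 1), 3, 2),
                          c("L1", "L2", "L3"), c("m1", "m2"))
  lf <- feature_table(matrix(1:4, 2, 2), c("L1", "L2"))  # L3 missing
  mf <- feature_table(matrix(1:4, 2, 2), c("m1", "m2"))
  ds <- align_dataset(ints, lf, mf, quiet = TRUE)
  expect_equal(nrow(ds$interactions$M), 2)
  expect_false("L3" %in% ds$interactions$lnc_ids)
  # edges of the dropped node are gone, total can only shrink
  expect_lte(sum(ds$interactions$M), sum(ints$M))

  # identical id sets: unchanged
  lf3 <- feature_table(matrix(1:6, 3, 2), c("L1", "L2", "L3"))
  ds3 <- align_dataset(ints, lf3, mf, quiet = TRUE)
  expect_equal(ds3$interactions$M, ints$M)

  # empty intersection errors
  expect_error(align_dataset(ints, feature_table(matrix(1, 1, 1), "other"),
                             mf, quiet = TRUE), "no lncRNA id matches")
})

test_that("alignment is idempotent", {
  ds <- tiny_dataset()
  again <- align_dataset(ds$interactions, ds$lnc_features, ds$mir_features,
                         quiet = TRUE)
  expect_equal(again$interactions$M, ds$interactions$M)
  expect_equal(again$lnc_features$F, ds$lnc_features$F)
  expect_equal(again$mir_features$F, ds$mir_features$F)
})

test_that("interaction sets round-trip through write and read", {
  ds <- tiny_dataset(seed = 7)
  path <- tempfile(fileext = ".tsv")
  write_interactions(ds$interactions, path)
  back <- read_interactions(path)
  # same edges, possibly different node order
  expect_equal(sum(back$M), sum(ds$interactions$M))
  common_l <- match(back$lnc_ids, ds$interactions$lnc_ids)
  common_m <- match(back$mir_ids, ds$interactions$mir_ids)
  sub <- ds$interactions$M[common_l, common_m, drop = FALSE]
  expect_equal(unname(back$M), unname(sub))
})

test_that("prediction output ranks unlabeled pairs by descending score", {
  ds <- structure(list(
    interactions = interaction_set(matrix(c(1, 0, 0, 0), 2, 2,
                                          byrow = TRUE),
                                   c("L1", "L2"), c("m1", "m2")),
    lnc_features = feature_table(matrix(1, 2, 2), c("L1", "L2")),
    mir_features = feature_table(matrix(1, 2, 2), c("m1", "m2"))
  ), class = "lm_dataset")
  scores <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  path <- tempfile()
  write_predictions(scores, ds, path, top_k = 3)
  out <- read.delim(path)
  expect_equal(out$lncRNA_id, c("L2", "L2", "L1"))
  expect_equal(out$miRNA_id, c("m2", "m1", "m2"))
  expect_equal(out$score, c(0.8, 0.2, 0.1))
  expect_equal(out$rank, 1:3)

  # single unlabeled pair
  ds1 <- structure(list(
    interactions = interaction_set(matrix(0, 1, 1), "L1", "m1"),
    lnc_features = feature_table(matrix(1, 1, 1), "L1"),
    mir_features = feature_table(matrix(1, 1, 1), "m1")
  ), class = "lm_dataset")
  write_predictions(matrix(0.7, 1, 1), ds1, path, top_k = 1)
  out1 <- read.delim(path)
  expect_equal(nrow(out1), 1)
  expect_equal(out1$rank, 1)

  # all pairs known: empty body
  ds_full <- structure(list(
    interactions = interaction_set(matrix(1, 1, 1), "L1", "m1"),
    lnc_features = ds1$lnc_features,
    mir_features = ds1$mir_features
  ), class = "lm_dataset")
  write_predictions(matrix(0.7, 1, 1), ds_full, path, top_k = 5)
  expect_equal(nrow(read.delim(path)), 0)

  expect_error(write_predictions(matrix(0, 3, 3), ds1, path), "shape")
})
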