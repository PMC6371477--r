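db_cached <- function() {
  cached("small_db", {
    ds <- small_clustered()
    build_database(ds$matrix, preprocessor_config(n_dims = 20),
                   labels = ds$labels, seed = 11)
  })
}

test_that("default build echoes the advertised configuration", {
  db <- db_cached()
  expect_s3_class(db, "CellDatabase")
  expect_equal(db$n_bits, 128L)
  expect_equal(db$n_lshashes, 4L)
  expect_length(db$hashes, 4L)
  expect_equal(nrow(db$metadata), 150L)
  for (h in db$hashes) expect_equal(ncol(h$mih$codes$codes), 150L)
  expect_error(build_database(small_clustered()$matrix, n_bits = 100),
               "n_bits")
})

test_that("identical seeds give identical databases", {
  ds <- small_clustered()
  cfg <- preprocessor_config(n_dims = 10)
  d1 <- build_database(ds$matrix, cfg, n_lshashes = 2, seed = 5)
  d2 <- build_database(ds$matrix, cfg, n_lshashes = 2, seed = 5)
  expect_identical(d1$preprocessor$projection, d2$preprocessor$projection)
  expect_identical(d1$hashes[[2]]$mih$codes$codes, d2$hashes[[2]]$mih$codes$codes)
})

test_that("a single-index database reduces to plain k-NN on that index", {
  ds <- small_clustered()
  db <- build_database(ds$matrix, preprocessor_config(n_dims = 10),
                       n_lshashes = 1, seed = 3)
  res <- query_cells(db, ds$matrix, k = 5)
  red <- apply_preprocessor(db$preprocessor, ds$matrix)
  qc <- encode_cells(red, db$hashes[[1]]$hyperplanes)
  direct <- knn_search(db$hashes[[1]]$mih, qc, 5)
  expect_identical(res$positions, direct$positions)
  expect_identical(res$distances, direct$distances)
})

test_that("database cells find themselves as nearest neighbors", {
  db <- db_cached()
  ds <- small_clustered()
  res <- query_cells(db, ds$matrix, k = 1)
  expect_gte(mean(res$positions[1, ] == seq_len(150)), 0.99)
  expect_true(all(res$distances[1, ] == 0))
  expect_true(all(res$cosines[1, ] == 1))
})

test_that("query ranking is deterministic and results well formed", {
  db <- db_cached()
  ds <- small_clustered()
  q <- expression_matrix(ds$matrix$counts[, 1:20], ds$matrix$gene_names,
                         ds$matrix$cell_names[1:20])
  r1 <- query_cells(db, q, k = 7)
  r2 <- query_cells(db, q, k = 7)
  expect_identical(r1, r2)
  expect_true(all(apply(r1$distances, 2, function(d) all(diff(d) >= 0))))
  expect_equal(dim(r1$positions), c(7L, 20L))
  tab <- as.data.frame(r1)
  expect_equal(nrow(tab), 140L)
  expect_named(tab, c("query_cell", "rank", "neighbor_cell", "hamming",
                      "cosine", "label"))
})

test_that("folding-in beats query-side standardization across batches", {
  ds2 <- cached("two_batch", make_dataset(
    synth_spec(n_genes = 800, n_cells = 240, n_clusters = 3,
               marker_genes_per_cluster = 80, n_batches = 2, seed = 77)))
  in1 <- ds2$batches == "batch1"
  ref <- expression_matrix(ds2$matrix$counts[, in1], ds2$matrix$gene_names,
                           ds2$matrix$cell_names[in1])
  qry <- expression_matrix(ds2$matrix$counts[, !in1], ds2$matrix$gene_names,
                           ds2$matrix$cell_names[!in1])
  db <- build_database(ref, preprocessor_config(n_dims = 20),
                       labels = ds2$labels[in1], seed = 19)
  fold <- query_cells(db, qry, k = 1)
  own <- query_cells(db, qry, k = 1, query_stats = TRUE)
  cons_fold <- consistency_score(ds2$labels[!in1], fold$neighbor_labels[1, ])
  cons_own <- consistency_score(ds2$labels[!in1], own$neighbor_labels[1, ])
  expect_gte(cons_fold, cons_own)
  expect_gt(cons_fold, 0.9)
})

test_that("label-agreement scores match their closed forms", {
  expect_equal(consistency_score(c("a", "b"), c("a", "b")), 1)
  expect_equal(consistency_score(c("a", "b"), c("c", "d")), 0)
  expect_equal(consistency_score(c("a", "b", "a", "b"), c("a", "b", "a", "c")), 0.75)
  expect_error(consistency_score("a", c("a", "b")), "equal length")

  expect_equal(cohens_kappa(c("x", "y", "x"), c("x", "y", "x")), 1)
  # 2x2 confusion [[20,5],[10,15]]: p_o = 0.7, p_e = 0.5 -> kappa = 0.4
  truth <- rep(c("A", "B"), c(25, 25))
  pred <- c(rep("A", 20), rep("B", 5), rep("A", 10), rep("B", 15))
  expect_equal(cohens_kappa(truth, pred), 0.4)
  # independent labels with matched marginals: kappa near 0
  big <- with_seed(13, list(a = sample(c("u", "v"), 4000, TRUE),
                            b = sample(c("u", "v"), 4000, TRUE)))
  expect_lt(abs(cohens_kappa(big$a, big$b)), 0.05)
  # degenerate single-label case: perfect agreement is 1, otherwise undefined
  expect_equal(cohens_kappa(c("z", "z"), c("z", "z")), 1)
})

test_that("stratified folds cover all cells with balanced labels", {
  labels <- rep(c("a", "b", "c"), c(50, 30, 20))
  folds <- split_folds(labels, 5, seed = 21)
  expect_true(all(folds %in% 1:5))
  expect_equal(as.vector(table(folds[labels == "a"])), rep(10, 5))
  expect_identical(split_folds(labels, 5, seed = 21), folds)
})
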