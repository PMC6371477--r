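test_that("feature selection finds the largest threshold keeping the floor", {
  # per-gene maxima 0, 0, 5, 9; fraction 0.5 of 4 genes -> at least 2 survive.
  # enumerating thresholds t = 0..9, the largest with >= 2 survivors is t = 5.
  counts <- rbind(c(0, 0), c(0, 0), c(5, 2), c(1, 9))
  x <- expression_matrix(counts, paste0("g", 1:4), c("c1", "c2"))
  sel <- select_features(x, preprocessor_config(min_features_fraction = 0.5))
  expect_identical(sel, c("g3", "g4"))
  # fraction 1.0 forces t = 0: everything kept
  expect_identical(select_features(x, preprocessor_config(min_features_fraction = 1)),
                   paste0("g", 1:4))
  # keep_genes overrides the threshold, drop_genes excludes
  cfg <- preprocessor_config(min_features_fraction = 0.5,
                             keep_genes = "g1", drop_genes = "g3")
  expect_identical(select_features(x, cfg), c("g1", "g4"))
})

test_that("cell normalization equalizes totals and names offending cells", {
  counts <- cbind(c(4, 6), c(5, 15))   # totals 10, 20
  out <- normalize_cells(counts, scale_factor = 10)
  expect_equal(out, cbind(c(4, 6), c(2.5, 7.5)))
  set.seed(5)
  r <- matrix(rpois(20 * 8, 4) + 1, 20, 8)
  n <- normalize_cells(r, 1e4)
  expect_equal(colSums(n), rep(1e4, 8), tolerance = 1e-9)
  bad <- cbind(c(1, 1), c(0, 0))
  expect_error(normalize_cells(bad, cell_names = c("ok", "empty")), "empty")
})

test_that("count transforms match their closed forms", {
  expect_equal(transform_counts(matrix(0), "log1p")[1], 0)
  expect_equal(transform_counts(matrix(0), "ftt")[1], 1)
  expect_equal(transform_counts(matrix(3), "ftt")[1], sqrt(3) + 2)
  m <- matrix(c(0, 1, 4, 9), 2)
  expect_equal(transform_counts(m, "log1p"), log1p(m))
  expect_equal(transform_counts(m, "ftt"), sqrt(m) + sqrt(m + 1))
  expect_error(transform_counts(matrix(-1)), "non-negative")
})

test_that("fitting standardizes features and the projection is lossless at low rank", {
  ds <- small_clustered()
  cfg <- preprocessor_config(n_dims = 10)
  P <- fit_preprocessor(ds$matrix, cfg, rng_seed = 1)
  # reconstruct the standardized matrix and check moments
  idx <- match(P$selected_genes, ds$matrix$gene_names)
  Y <- normalize_cells(as.matrix(ds$matrix$counts)[idx, ], cfg$scale_factor)
  Z <- transform_counts(Y, cfg$transform)
  Zs <- (Z - P$feature_means) / P$feature_sds
  expect_lt(max(abs(rowMeans(Zs))), 1e-8)
  expect_lt(max(abs(apply(Zs, 1, stats::var) - 1)), 1e-6)

  # exact rank-3 input, D = 3: reduced space preserves pairwise cosines
  set.seed(2)
  B <- matrix(rnorm(40 * 3), 40, 3) %*% matrix(rnorm(3 * 12), 3, 12)
  sv <- randomized_svd(B, 3, rng_seed = 3)
  red <- t(sv$U) %*% B
  cos_of <- function(M) {
    nrm <- sqrt(colSums(M^2))
    crossprod(M) / tcrossprod(nrm)
  }
  expect_equal(cos_of(red), cos_of(B), tolerance = 1e-6)
})

test_that("fit is deterministic and guards degenerate inputs", {
  ds <- small_clustered()
  cfg <- preprocessor_config(n_dims = 8)
  P1 <- fit_preprocessor(ds$matrix, cfg, rng_seed = 4)
  P2 <- fit_preprocessor(ds$matrix, cfg, rng_seed = 4)
  expect_identical(P1$projection, P2$projection)
  one <- expression_matrix(matrix(1:3, 3, 1), paste0("g", 1:3), "c1")
  expect_error(fit_preprocessor(one, preprocessor_config(n_dims = 1)),
               "two cells")
  # constant feature is dropped with a warning, not an error.  Column totals
  # are equalized so the constant row stays constant after normalization.
  set.seed(9)
  counts <- matrix(rpois(30 * 6, 8), 30, 6)
  filler <- max(colSums(counts)) + 10 - colSums(counts)
  counts <- rbind(counts, filler, rep(5, 6))
  x <- expression_matrix(counts, paste0("g", 1:32), paste0("c", 1:6))
  cfg1 <- preprocessor_config(min_features_fraction = 1, n_dims = 3)
  expect_warning(P <- fit_preprocessor(x, cfg1, rng_seed = 1), "zero-variance")
  expect_false("g32" %in% P$selected_genes)
})

test_that("applying the preprocessor folds queries into the reference space", {
  ds <- small_clustered()
  cfg <- preprocessor_config(n_dims = 10)
  P <- fit_preprocessor(ds$matrix, cfg, rng_seed = 1)
  red <- P$reduced
  out <- apply_preprocessor(P, ds$matrix)
  expect_equal(unname(out), unname(red), tolerance = 1e-10)
  # permuted cells give permuted output
  perm <- rev(seq_along(ds$matrix$cell_names))
  qp <- expression_matrix(ds$matrix$counts[, perm], ds$matrix$gene_names,
                          ds$matrix$cell_names[perm])
  expect_equal(unname(apply_preprocessor(P, qp)), unname(out[, perm]),
               tolerance = 1e-10)
  # an extra unshared gene changes nothing (alignment drops it)
  q2 <- expression_matrix(rbind(as.matrix(ds$matrix$counts), 3),
                          c(ds$matrix$gene_names, "unshared"),
                          ds$matrix$cell_names)
  expect_equal(apply_preprocessor(P, q2), out, tolerance = 1e-10)
  # library-size invariance: a common positive scaling is absorbed
  q3 <- expression_matrix(ds$matrix$counts * 3, ds$matrix$gene_names,
                          ds$matrix$cell_names)
  expect_equal(apply_preprocessor(P, q3), out, tolerance = 1e-10)
})
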