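test_that("compressed counts decompress to the exact original columns", {
  ds <- small_clustered()
  store <- compress_counts(ds$matrix)
  for (j in c(1L, 50L, 150L))
    expect_identical(decompress_cell(store, j),
                     stats::setNames(as.integer(ds$matrix$counts[, j]),
                                     ds$matrix$gene_names))
  expect_identical(decompress_cell(store, ds$matrix$cell_names[3]),
                   decompress_cell(store, 3L))
  # sparse input round-trips too
  sp <- expression_matrix(Matrix::Matrix(as.matrix(ds$matrix$counts[, 1:5]),
                                         sparse = TRUE),
                          ds$matrix$gene_names, ds$matrix$cell_names[1:5])
  expect_identical(decompress_cell(compress_counts(sp), 2L),
                   decompress_cell(store, 2L))
  expect_error(decompress_cell(store, "nope"), "unknown cell")
})

deg_db <- function() {
  cached("deg_db", {
    ds <- small_clustered()
    build_database(ds$matrix, preprocessor_config(n_dims = 20),
                   labels = ds$labels, seed = 23, store_counts = TRUE)
  })
}

db_cached_noraw <- function() {
  cached("small_db_noraw", {
    ds <- small_clustered()
    build_database(ds$matrix, preprocessor_config(n_dims = 10), seed = 11)
  })
}

test_that("neighborhood means match direct arithmetic on scaled columns", {
  db <- deg_db()
  ds <- small_clustered()
  # k = 1: the neighborhood is the cell itself; with n_u = n_v the mean is
  # the raw column
  tot <- colSums(as.matrix(ds$matrix$counts))
  lam <- neighborhood_mean(db, 4L, k = 1, n_u = tot[4])
  expect_equal(unname(lam), as.numeric(ds$matrix$counts[, 4]))
  # k = 5: hand-compute the mean of the scaled neighbor columns
  nb <- cellhash:::db_self_neighbors(db, 4L, 5L)
  n_u <- 1234
  hand <- rowMeans(vapply(nb$positions, function(p)
    as.numeric(ds$matrix$counts[, p]) * n_u / tot[p], numeric(600)))
  expect_equal(unname(neighborhood_mean(db, 4L, k = 5, n_u = n_u)), hand)
  expect_true(4L %in% nb$positions)   # the cell is in its own neighborhood
})

test_that("Poisson tails agree with direct pmf summation", {
  t1 <- poisson_tails(0, 2)
  expect_equal(t1$lower, exp(-2))
  expect_equal(t1$upper, 1)
  t0 <- poisson_tails(0, 0)
  expect_equal(c(t0$lower, t0$upper), c(1, 1))
  expect_equal(poisson_tails(3, 0)$upper, 0)
  t2 <- poisson_tails(7, 2)
  expect_equal(t2$upper, 1 - sum(stats::dpois(0:6, 2)), tolerance = 1e-12)
  # summation oracle across a grid, including large means
  for (lam in c(0.3, 2, 17, 100)) {
    for (y in c(0L, 1L, 5L, 40L, 130L)) {
      tt <- poisson_tails(y, lam)
      expect_equal(tt$lower, sum(stats::dpois(0:y, lam)), tolerance = 1e-10)
      expect_equal(tt$upper, 1 - sum(stats::dpois(seq_len(y) - 1, lam)),
                   tolerance = 1e-10)
      expect_gte(tt$lower + tt$upper, 1 - 1e-12)
    }
  }
  # monotonicity in y
  ys <- 0:60
  tails <- poisson_tails(ys, 12)
  expect_true(all(diff(tails$lower) >= 0))
  expect_true(all(diff(tails$upper) <= 0))
  expect_error(poisson_tails(-1, 2), "non-negative")
})

test_that("DEG detection flags spiked genes and stays quiet at the mode", {
  db <- deg_db()
  ds <- small_clustered()
  j <- 10L
  y <- stats::setNames(as.numeric(ds$matrix$counts[, j]), ds$matrix$gene_names)
  res <- detect_degs(db, y, j, k = 10)
  expect_s3_class(res, "DEGResult")
  # a cell compared against its own neighborhood should flag (almost) nothing
  expect_lte(sum(res$direction != "none"), 2L)
  expect_true(all(res$tail_lower[res$direction == "negative"] < 1e-4))
  expect_true(all(res$tail_upper[res$direction == "positive"] < 1e-4))
  # spike one moderately expressed gene to 10x its neighborhood mean
  g <- res$gene[which(res$lambda >= 5)[1]]
  y2 <- y
  y2[g] <- round(10 * res$lambda[res$gene == g])
  res2 <- detect_degs(db, y2, j, k = 10)
  expect_identical(res2$direction[res2$gene == g], "positive")
  # missing raw counts produce a actionable error
  db0 <- db_cached_noraw()
  expect_error(detect_degs(db0, y, j), "store_counts")
})

test_that("the neighborhood mean is an unbiased estimator under the model", {
  # neighbors j draw Pois(beta_j * lambda) with beta_j set by their totals;
  # the scaled mean should converge to beta_u * lambda
  lambda <- c(0.5, 2, 8, 30)
  betas <- with_seed(31, runif(10, 0.5, 2))
  n_u <- 1
  reps <- 4000
  est <- matrix(0, reps, length(lambda))
  with_seed(32, for (r in seq_len(reps)) {
    draws <- vapply(betas, function(b) rpois(length(lambda), b * lambda),
                    numeric(length(lambda)))
    est[r, ] <- rowMeans(draws / rep(betas, each = length(lambda)) * n_u)
  })
  se <- apply(est, 2, stats::sd) / sqrt(reps)
  expect_true(all(abs(colMeans(est) - n_u * lambda) < 4 * se))
})

test_that("DEG calls are invariant to a common neighbor library scaling", {
  ds <- small_clustered()
  x2 <- expression_matrix(ds$matrix$counts * 3L, ds$matrix$gene_names,
                          ds$matrix$cell_names)
  db1 <- deg_db()
  db2 <- build_database(x2, preprocessor_config(n_dims = 20),
                        labels = ds$labels, seed = 23, store_counts = TRUE)
  y <- stats::setNames(as.numeric(ds$matrix$counts[, 8]), ds$matrix$gene_names)
  r1 <- detect_degs(db1, y, 8L)
  r2 <- detect_degs(db2, y, 8L)
  expect_equal(r1$lambda, r2$lambda, tolerance = 1e-12)
  expect_identical(r1$direction, r2$direction)
})
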