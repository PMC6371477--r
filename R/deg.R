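#' Compress raw counts with per-cell random access
#'
#' Stores each cell's raw count column as an independently gzip-compressed
#' block so single cells can be decompressed on request without touching the
#' rest of the matrix.
#'
#' @param X an [expression_matrix()].
#' @return A list of class `CompressedCounts` with `gene_names`,
#'   `cell_names`, `totals`, and `blocks` (one raw vector per cell).
#' @export
compress_counts <- function(X) {
  N <- length(X$cell_names)
  sparse <- is(X$counts, "sparseMatrix")
  blocks <- vector("list", N)
  totals <- numeric(N)
  for (j in seq_len(N)) {
    col <- if (sparse) as.integer(X$counts[, j]) else as.integer(X$counts[, j])
    totals[j] <- sum(col)
    blocks[[j]] <- memCompress(writeBin(col, raw(), size = 4L), type = "gzip")
  }
  structure(list(gene_names = X$gene_names, cell_names = X$cell_names,
                 totals = totals, blocks = blocks),
            class = "CompressedCounts")
}

#' @method print CompressedCounts
#' @export
print.CompressedCounts <- function(x, ...) {
  bytes <- sum(vapply(x$blocks, length, 1L))
  cat(sprintf("CompressedCounts: %d genes x %d cells (%.1f kB compressed)\n",
              length(x$gene_names), length(x$cell_names), bytes / 1024))
  invisible(x)
}

#' Decompress one cell's raw counts
#'
#' @param store a [compress_counts()] `CompressedCounts`.
#' @param cell cell index or cell name.
#' @return Named integer vector of raw counts for that cell.
#' @export
decompress_cell <- function(store, cell) {
  j <- if (is.character(cell)) match(cell, store$cell_names) else as.integer(cell)
  if (is.na(j) || j < 1L || j > length(store$cell_names))
    stopf("unknown cell '%s'", as.character(cell))
  col <- readBin(memDecompress(store$blocks[[j]], type = "gzip"),
                 "integer", n = length(store$gene_names), size = 4L)
  names(col) <- store$gene_names
  col
}

# k-NN of a database cell among the database cells themselves, by total
# Hamming distance over the L stored code sets (the cell itself is returned
# first at distance 0).
db_self_neighbors <- function(db, v, k) {
  j <- if (is.character(v)) match(v, db$metadata$cell) else as.integer(v)
  if (is.na(j) || j < 1L || j > nrow(db$metadata))
    stopf("unknown database cell '%s'", as.character(v))
  qcodes <- lapply(db$hashes, function(h)
    bitcodes(h$mih$codes$codes[, j, drop = FALSE], db$n_bits))
  res <- query_codes(db, qcodes, k)
  list(positions = res$positions[, 1L], distances = res$distances[, 1L])
}

#' Neighborhood mean expression for a database cell
#'
#' Retrieves the k nearest database neighbors of cell `v` (by total Hamming
#' distance over the stored hash codes; `v` itself is in the database and is
#' always included), rescales each neighbor's raw counts so its total equals
#' the query library size `n_u`, and returns the per-gene arithmetic mean.
#' Under a Poisson count model with capture efficiencies proportional to
#' library sizes, this mean is an unbiased estimator of the query cell's
#' expected counts.
#'
#' @param db a `CellDatabase` built with `store_counts = TRUE`.
#' @param v database cell (index or name) the query was matched to.
#' @param k neighborhood size (default 10).
#' @param n_u total count (library size) of the query cell.
#' @return Named numeric vector of per-gene means, one per database gene.
#' @export
neighborhood_mean <- function(db, v, k = 10L, n_u) {
  if (is.null(db$raw_store))
    stop("database has no raw counts; rebuild with store_counts = TRUE ",
         "(CLI: --store-counts)")
  if (k < 1L) stop("k must be >= 1")
  nb <- db_self_neighbors(db, v, k)
  acc <- NULL
  for (pos in nb$positions) {
    col <- decompress_cell(db$raw_store, pos)
    scaled <- col * (n_u / db$raw_store$totals[pos])
    acc <- if (is.null(acc)) scaled else acc + scaled
  }
  acc / length(nb$positions)
}

#' Exact Poisson tail probabilities
#'
#' Lower tail `P(Y <= y)` and upper tail `P(Y >= y)` for `Y ~ Poisson(lambda)`,
#' computed via the regularized incomplete gamma relation underlying
#' `ppois()` for numerical stability at large means.  Both tails include the
#' point mass at `y`, so they sum to at least 1.  `lambda = 0` is treated as
#' a point mass at zero.
#'
#' @param y observed count(s), non-negative integers.
#' @param lambda Poisson mean(s), non-negative.
#' @return A list with vectors `lower` and `upper`.
#' @export
poisson_tails <- function(y, lambda) {
  if (any(y < 0) || any(y != floor(y))) stop("y must be non-negative integers")
  if (any(lambda < 0)) stop("lambda must be non-negative")
  list(lower = ppois(y, lambda),
       upper = ppois(y - 1, lambda, lower.tail = FALSE))
}

#' Detect differentially expressed genes for one query cell
#'
#' Compares the raw counts of a query cell against the Poisson model implied
#' by the neighborhood of its matched database cell: the per-gene mean is
#' estimated by [neighborhood_mean()] with the query's library size, and
#' both Poisson tails are computed per gene.  Genes with lower tail < alpha
#' are flagged negative (under-expressed in the query relative to the
#' neighborhood), genes with upper tail < alpha positive.  The tail
#' probabilities are reported raw, without multiple-testing correction;
#' tighten `alpha` to taste.
#'
#' @param db a `CellDatabase` built with `store_counts = TRUE`.
#' @param query_counts named vector of the query cell's raw counts (names
#'   are gene names; genes absent from the database are ignored, database
#'   genes absent from the query count as zero).
#' @param matched_cell database cell (index or name) the query was matched
#'   to, e.g. its nearest neighbor from [query_cells()].
#' @param k neighborhood size (default 10).
#' @param alpha flagging threshold on the tail probability (default 1e-4).
#' @return A data.frame of class `DEGResult` with one row per database
#'   gene: gene, y, lambda, tail_lower, tail_upper, direction
#'   (`"negative"`, `"positive"`, or `"none"`).
#' @export
detect_degs <- function(db, query_counts, matched_cell, k = 10L, alpha = 1e-4) {
  if (is.null(db$raw_store))
    stop("database has no raw counts; rebuild with store_counts = TRUE ",
         "(CLI: --store-counts)")
  if (is.null(names(query_counts)))
    stop("query_counts must be a named vector (gene names)")
  if (any(query_counts < 0)) stop("query_counts must be non-negative")
  genes <- db$raw_store$gene_names
  n_u <- sum(query_counts)
  y <- query_counts[match(genes, trimws(names(query_counts)))]
  y[is.na(y)] <- 0
  lambda <- neighborhood_mean(db, matched_cell, k = k, n_u = n_u)
  tails <- poisson_tails(as.numeric(y), as.numeric(lambda))
  direction <- rep("none", length(genes))
  direction[tails$lower < alpha] <- "negative"
  direction[tails$upper < alpha] <- "positive"
  out <- data.frame(gene = genes, y = as.numeric(y),
                    lambda = as.numeric(lambda),
                    tail_lower = tails$lower, tail_upper = tails$upper,
                    direction = direction, stringsAsFactors = FALSE)
  class(out) <- c("DEGResult", "data.frame")
  out
}

#' @method print DEGResult
#' @export
print.DEGResult <- function(x, ...) {
  flagged <- x$direction != "none"
  cat(sprintf("DEGResult: %d genes tested, %d flagged (%d up, %d down)\n",
              nrow(x), sum(flagged), sum(x$direction == "positive"),
              sum(x$direction == "negative")))
  if (any(flagged)) print.data.frame(x[flagged, , drop = FALSE], row.names = FALSE)
  invisible(x)
}
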