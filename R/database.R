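#' Build a searchable cell database
#'
#' Fits the preprocessor on the reference matrix, encodes the reduced
#' profiles with `n_lshashes` independent orthogonalized hyperplane sets
#' (seeded `seed + 0 ... seed + L - 1` so a build is reproducible from one
#' seed), and builds one multi-index hash per code set.  Optionally stores
#' the raw counts in a per-cell compressed store so differential expression
#' can be computed post hoc.
#'
#' @param X reference [expression_matrix()].
#' @param config a [preprocessor_config()].
#' @param n_bits bits per hash code; one of 64, 128, 256, 512 (default 128).
#' @param n_lshashes number L of independent hash indexes (default 4).
#' @param seed integer build seed.
#' @param labels optional per-cell labels (length N) stored in the metadata.
#' @param store_counts logical; keep a compressed copy of the raw counts
#'   (required by [detect_degs()]).
#' @param mih_s optional subcode length passed to [build_mih()].
#' @return A list of class `CellDatabase`.
#' @export
build_database <- function(X, config = preprocessor_config(), n_bits = 128L,
                           n_lshashes = 4L, seed = 0L, labels = NULL,
                           store_counts = FALSE, mih_s = NULL) {
  if (!n_bits %in% c(64L, 128L, 256L, 512L))
    stop("n_bits must be one of 64, 128, 256, 512")
  if (n_lshashes < 1L) stop("n_lshashes must be >= 1")
  if (!is.null(labels) && length(labels) != length(X$cell_names))
    stop("labels length must equal the number of cells")
  P <- fit_preprocessor(X, config, rng_seed = seed)
  reduced <- P$reduced
  P$reduced <- NULL               # not needed after encoding; keeps files small
  D <- nrow(reduced)
  hashes <- vector("list", n_lshashes)
  for (l in seq_len(n_lshashes)) {
    H <- generate_hyperplanes(D, n_bits, orthogonalize = TRUE,
                              rng_seed = seed + l - 1L)
    codes <- encode_cells(reduced, H)
    hashes[[l]] <- list(hyperplanes = H, mih = build_mih(codes, s = mih_s))
  }
  metadata <- data.frame(cell = X$cell_names, stringsAsFactors = FALSE)
  if (!is.null(labels)) metadata$label <- as.character(labels)
  raw_store <- if (store_counts) compress_counts(X) else NULL
  structure(list(preprocessor = P, hashes = hashes, metadata = metadata,
                 raw_store = raw_store, n_bits = as.integer(n_bits),
                 n_lshashes = as.integer(n_lshashes),
                 build_seed = as.integer(seed), format_version = 1L),
            class = "CellDatabase")
}

#' @method print CellDatabase
#' @export
print.CellDatabase <- function(x, ...) {
  cat(sprintf(paste0("CellDatabase: %d cells, %d selected features, D=%d, ",
                     "T=%d bits x L=%d indexes%s\n"),
              nrow(x$metadata), length(x$preprocessor$selected_genes),
              nrow(x$preprocessor$projection), x$n_bits, x$n_lshashes,
              if (is.null(x$raw_store)) "" else ", raw counts stored"))
  invisible(x)
}

#' @method summary CellDatabase
#' @export
summary.CellDatabase <- function(object, ...) {
  cat(sprintf("cells:             %d\n", nrow(object$metadata)))
  cat(sprintf("selected features: %d\n", length(object$preprocessor$selected_genes)))
  cat(sprintf("reduced dims (D):  %d\n", nrow(object$preprocessor$projection)))
  cat(sprintf("bits per code (T): %d\n", object$n_bits))
  cat(sprintf("hash indexes (L):  %d\n", object$n_lshashes))
  cat(sprintf("labels:            %s\n",
              if ("label" %in% names(object$metadata)) "present" else "absent"))
  cat(sprintf("raw counts:        %s\n",
              if (is.null(object$raw_store)) "absent" else "stored (compressed)"))
  invisible(object)
}

# Search the L indexes with precomputed query codes (list of BitCodes, one
# per index) and aggregate candidates by total Hamming distance.
query_codes <- function(db, qcodes, k) {
  L <- db$n_lshashes
  nq <- ncol(qcodes[[1L]]$codes)
  N <- nrow(db$metadata)
  kfind <- min(k, N)
  per_index <- lapply(seq_len(L), function(l)
    knn_search(db$hashes[[l]]$mih, qcodes[[l]], kfind))
  positions <- matrix(0L, kfind, nq)
  distances <- matrix(0L, kfind, nq)
  for (q in seq_len(nq)) {
    cand <- unique(unlist(lapply(per_index, function(r) r$positions[, q])))
    total <- integer(length(cand))
    for (l in seq_len(L)) {
      total <- total + hamming_subset_cpp(db$hashes[[l]]$mih$codes$codes,
                                          qcodes[[l]]$codes[, q],
                                          cand - 1L)
    }
    ord <- order(total, cand)[seq_len(kfind)]
    positions[, q] <- cand[ord]
    distances[, q] <- total[ord]
  }
  list(positions = positions, distances = distances)
}

#' Query a cell database for nearest-neighbor cells
#'
#' Preprocesses the query cells with the database's fitted preprocessor
#' (folding-in), hashes them with each of the L hyperplane sets, retrieves k
#' candidates per index, and re-ranks the candidate union by the total
#' Hamming distance summed over all L codes (computed for every candidate,
#' including those found by only some indexes).  Ties are broken by
#' ascending database position.  Cosine similarities are estimated from the
#' total distances out of `T * L` bits.
#'
#' @param db a [build_database()] `CellDatabase`.
#' @param Q query [expression_matrix()].
#' @param k number of neighbors to return per query cell (default 10).
#' @param query_stats standardize queries with their own statistics instead
#'   of the reference statistics (see [apply_preprocessor()]).
#' @return A list of class `SearchResult` with `positions`, `distances`
#'   (total Hamming, out of `T * L`), `cosines`, `neighbor_names`, and
#'   `neighbor_labels` (if the database has labels); each a
#'   `min(k, N)` x n_queries matrix, plus `query_names` and `total_bits`.
#' @export
query_cells <- function(db, Q, k = 10L, query_stats = FALSE) {
  if (k < 1L) stop("k must be >= 1")
  reduced <- apply_preprocessor(db$preprocessor, Q, query_stats = query_stats)
  qcodes <- lapply(db$hashes, function(h) encode_cells(reduced, h$hyperplanes))
  res <- query_codes(db, qcodes, k)
  finish_search_result(db, res, Q$cell_names)
}

finish_search_result <- function(db, res, query_names) {
  total_bits <- db$n_bits * db$n_lshashes
  out <- list(positions = res$positions,
              distances = res$distances,
              cosines = cosine_from_hamming(res$distances, total_bits),
              neighbor_names = matrix(db$metadata$cell[res$positions],
                                      nrow(res$positions)),
              query_names = query_names,
              total_bits = total_bits)
  if ("label" %in% names(db$metadata))
    out$neighbor_labels <- matrix(db$metadata$label[res$positions],
                                  nrow(res$positions))
  structure(out, class = "SearchResult")
}

#' @method print SearchResult
#' @export
print.SearchResult <- function(x, ...) {
  cat(sprintf("SearchResult: %d quer%s, k=%d (distances out of %d bits)\n",
              ncol(x$positions), if (ncol(x$positions) == 1) "y" else "ies",
              nrow(x$positions), x$total_bits))
  invisible(x)
}

#' Turn a search result into a long-format table
#'
#' @param x a `SearchResult`.
#' @param ... unused.
#' @return A data.frame with columns query_cell, rank, neighbor_cell,
#'   hamming, cosine, and label when present.
#' @method as.data.frame SearchResult
#' @export
as.data.frame.SearchResult <- function(x, ...) {
  k <- nrow(x$positions); nq <- ncol(x$positions)
  out <- data.frame(
    query_cell = rep(x$query_names, each = k),
    rank = rep(seq_len(k), nq),
    neighbor_cell = as.vector(x$neighbor_names),
    hamming = as.vector(x$distances),
    cosine = as.vector(x$cosines),
    stringsAsFactors = FALSE)
  if (!is.null(x$neighbor_labels)) out$label <- as.vector(x$neighbor_labels)
  out
}

#' Consistency score of transferred labels
#'
#' Fraction of positions where the two label vectors agree; 1 is perfect
#' agreement, 0 none.
#'
#' @param true_labels,predicted_labels equal-length vectors.
#' @return A number in `[0, 1]`.
#' @export
consistency_score <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  mean(as.character(true_labels) == as.character(predicted_labels))
}

#' Cohen's kappa for transferred labels
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement `p_e` computed from the marginal label frequencies; 1 is
#' perfect agreement, 0 the level expected under independent assignment.
#'
#' @param true_labels,predicted_labels equal-length vectors.
#' @return Kappa.  When both vectors use one single label (`p_e = 1`),
#'   perfect agreement returns 1; otherwise this is an error.
#' @export
cohens_kappa <- function(true_labels, predicted_labels) {
  a <- as.character(true_labels); b <- as.character(predicted_labels)
  if (length(a) != length(b)) stop("label vectors must have equal length")
  p_o <- mean(a == b)
  lev <- union(unique(a), unique(b))
  pa <- tabulate(match(a, lev), length(lev)) / length(a)
  pb <- tabulate(match(b, lev), length(lev)) / length(b)
  p_e <- sum(pa * pb)
  if (p_e >= 1 - 1e-12) {
    if (p_o >= 1 - 1e-12) return(1)
    stop("kappa undefined: expected agreement is 1 but observed is not")
  }
  (p_o - p_e) / (1 - p_e)
}

#' Stratified fold assignment for self-mapping evaluation
#'
#' Assigns each cell to one of `n_folds` folds, stratified by label so every
#' fold holds roughly the same label mix.
#'
#' @param labels per-cell labels.
#' @param n_folds number of folds (default 5).
#' @param seed RNG seed.
#' @return Integer fold assignment in `1..n_folds`, one per cell.
#' @export
split_folds <- function(labels, n_folds = 5L, seed = 0L) {
  labels <- as.character(labels)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Fivefold self-mapping evaluation
#'
#' For each fold, builds a database from the other folds' cells, queries the
#' held-out fifth, transfers the nearest neighbor's label, and scores the
#' transfer by consistency and Cohen's kappa.
#'
#' @param X an [expression_matrix()].
#' @param labels per-cell labels (length N).
#' @param n_folds number of folds (default 5).
#' @param k neighbors retrieved per query (default 10; only the nearest is
#'   used for scoring).
#' @param seed seed controlling the fold split and each fold's build.
#' @param ... passed to [build_database()] (e.g. `config`, `n_bits`,
#'   `n_lshashes`).
#' @return A data.frame with one row per fold: fold, n_query, consistency,
#'   kappa.
#' @export
self_map_eval <- function(X, labels, n_folds = 5L, k = 10L, seed = 0L, ...) {
  labels <- as.character(labels)
  folds <- split_folds(labels, n_folds, seed)
  out <- data.frame(fold = seq_len(n_folds), n_query = 0L,
                    consistency = NA_real_, kappa = NA_real_)
  for (f in seq_len(n_folds)) {
    te <- folds == f
    ref <- expression_matrix(X$counts[, !te, drop = FALSE],
                             X$gene_names, X$cell_names[!te])
    qry <- expression_matrix(X$counts[, te, drop = FALSE],
                             X$gene_names, X$cell_names[te])
    db <- build_database(ref, labels = labels[!te], seed = seed + f, ...)
    res <- query_cells(db, qry, k = k)
    pred <- res$neighbor_labels[1L, ]
    out$n_query[f] <- sum(te)
    out$consistency[f] <- consistency_score(labels[te], pred)
    out$kappa[f] <- cohens_kappa(labels[te], pred)
  }
  out
}
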