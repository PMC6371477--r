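#' Preprocessing configuration
#'
#' Parameters for the five-step preprocessing pipeline applied before
#' hashing: feature selection by maximum count, cell-wise library-size
#' normalization, a variance-stabilizing transform, per-feature
#' standardization, and projection onto a low-dimensional subspace.
#'
#' @param min_features_fraction fraction of features the maximum-count
#'   threshold must retain, in (0, 1] (default 0.10).
#' @param transform `"log1p"` (log(x+1), default) or `"ftt"` (Freeman-Tukey,
#'   sqrt(x) + sqrt(x+1), variance-stabilizing under Poisson noise).
#' @param n_dims dimension D of the reduced space (default 50).
#' @param keep_genes,drop_genes optional gene-name lists force-retained or
#'   force-excluded after thresholding.
#' @param scale_factor common post-normalization library size (default 1e4
#'   counts per cell).
#' @return A list of class `PreprocessorConfig`.
#' @export
preprocessor_config <- function(min_features_fraction = 0.10,
                                transform = c("log1p", "ftt"),
                                n_dims = 50L,
                                keep_genes = NULL,
                                drop_genes = NULL,
                                scale_factor = 1e4) {
  transform <- match.arg(transform)
  if (min_features_fraction <= 0 || min_features_fraction > 1)
    stop("min_features_fraction must be in (0, 1]")
  if (n_dims < 1L) stop("n_dims must be >= 1")
  if (scale_factor <= 0) stop("scale_factor must be positive")
  structure(list(min_features_fraction = min_features_fraction,
                 transform = transform, n_dims = as.integer(n_dims),
                 keep_genes = keep_genes, drop_genes = drop_genes,
                 scale_factor = scale_factor),
            class = "PreprocessorConfig")
}

#' Select features by maximum count
#'
#' Retains genes whose per-gene maximum count across cells is at least `t`,
#' where `t` is the largest integer threshold such that at least
#' `ceil(min_features_fraction * M)` genes survive.  `keep_genes` /
#' `drop_genes` overrides are applied after thresholding.
#'
#' @param X an [expression_matrix()].
#' @param config a [preprocessor_config()].
#' @return Character vector of selected gene names, in matrix order.
#' @export
select_features <- function(X, config = preprocessor_config()) {
  M <- length(X$gene_names)
  if (M == 0L) stop("empty expression matrix")
  maxc <- apply_gene_max(X$counts)
  floor_n <- ceiling(config$min_features_fraction * M)
  # largest integer t with at least floor_n surviving genes
  t_max <- max(maxc)
  t_sel <- 0L
  for (t in seq_len(t_max)) {
    if (sum(maxc >= t) >= floor_n) t_sel <- t else break
  }
  keep <- maxc >= t_sel
  if (!is.null(config$keep_genes))
    keep <- keep | X$gene_names %in% trimws(config$keep_genes)
  if (!is.null(config$drop_genes))
    keep <- keep & !(X$gene_names %in% trimws(config$drop_genes))
  if (!any(keep)) stop("feature selection excluded all genes")
  X$gene_names[keep]
}

apply_gene_max <- function(counts) {
  if (is(counts, "sparseMatrix")) {
    m <- as(counts, "RsparseMatrix")
    out <- numeric(nrow(counts))
    ptr <- m@p
    for (i in seq_len(nrow(counts))) {
      vals <- m@x[(ptr[i] + 1L):ptr[i + 1L]]
      out[i] <- if (ptr[i + 1L] > ptr[i]) max(vals) else 0
    }
    out
  } else {
    apply(counts, 1L, max)
  }
}

#' Normalize cells to a common library size
#'
#' Scales each column (cell) so all column totals equal `scale_factor`.
#'
#' @param counts count matrix (genes x cells), dense or sparse.
#' @param scale_factor target total per cell.
#' @param cell_names optional names used in error messages.
#' @return Dense or sparse real matrix with equal column sums.
#' @export
normalize_cells <- function(counts, scale_factor = 1e4, cell_names = NULL) {
  totals <- if (is(counts, "sparseMatrix")) Matrix::colSums(counts) else colSums(counts)
  if (any(totals <= 0)) {
    bad <- which(totals <= 0)[1L]
    nm <- if (!is.null(cell_names)) cell_names[bad] else as.character(bad)
    stopf("cell '%s' has zero total count and cannot be normalized", nm)
  }
  sweep_cols(counts, scale_factor / totals)
}

sweep_cols <- function(m, f) {
  if (is(m, "sparseMatrix")) m %*% Matrix::Diagonal(x = f)
  else m * rep(f, each = nrow(m))
}

#' Variance-stabilizing transforms for counts
#'
#' Elementwise `log(x + 1)` or the Freeman-Tukey transform
#' `sqrt(x) + sqrt(x + 1)`.
#'
#' @param Y non-negative real matrix.
#' @param transform `"log1p"` or `"ftt"`.
#' @return Transformed matrix (dense).
#' @export
transform_counts <- function(Y, transform = c("log1p", "ftt")) {
  transform <- match.arg(transform)
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("transform_counts requires non-negative input")
  if (transform == "log1p") log1p(Y) else sqrt(Y) + sqrt(Y + 1)
}

#' Fit the preprocessing pipeline on a reference matrix
#'
#' Runs feature selection, normalization, the chosen transform, per-feature
#' standardization (mean 0, unit unbiased variance; features with reference
#' sd below 1e-8 are dropped with a warning), and a randomized SVD of the
#' standardized matrix.  The projection consists of the top-`n_dims`
#' singular directions of the standardized reference; the reduced reference
#' matrix (D x N) is returned alongside.
#'
#' @param X reference [expression_matrix()].
#' @param config a [preprocessor_config()].
#' @param rng_seed seed for the randomized SVD.
#' @return A list of class `Preprocessor` with elements `selected_genes`,
#'   `feature_means`, `feature_sds`, `projection` (D x n_features),
#'   `config`, and `reduced` (D x N reduced reference matrix).
#' @export
fit_preprocessor <- function(X, config = preprocessor_config(), rng_seed = 0L) {
  if (length(X$cell_names) < 2L)
    stop("at least two cells are required to fit the preprocessor")
  sel <- select_features(X, config)
  idx <- match(sel, X$gene_names)
  Y <- X$counts[idx, , drop = FALSE]
  Y <- normalize_cells(Y, config$scale_factor, X$cell_names)
  Z <- transform_counts(Y, config$transform)
  mu <- rowMeans(Z)
  sds <- apply(Z, 1L, sd)           # unbiased (n-1) convention
  ok <- sds >= 1e-8
  if (!all(ok)) {
    warning(sprintf("dropping %d zero-variance feature(s) before projection",
                    sum(!ok)))
    sel <- sel[ok]; Z <- Z[ok, , drop = FALSE]
    mu <- mu[ok]; sds <- sds[ok]
  }
  D <- config$n_dims
  if (length(sel) < D)
    stopf("only %d usable features but n_dims = %d", length(sel), D)
  Zs <- (Z - mu) / sds
  sv <- randomized_svd(Zs, D, rng_seed = rng_seed)
  projection <- t(sv$U)             # D x n_features
  reduced <- projection %*% Zs      # D x N == diag(S) V^T
  structure(list(selected_genes = sel, feature_means = mu, feature_sds = sds,
                 projection = projection, config = config, reduced = reduced),
            class = "Preprocessor")
}

#' @method print Preprocessor
#' @export
print.Preprocessor <- function(x, ...) {
  cat(sprintf("Preprocessor: %d features -> %d dims (%s transform)\n",
              length(x$selected_genes), nrow(x$projection), x$config$transform))
  invisible(x)
}

#' Apply a fitted preprocessor to query cells
#'
#' Aligns query genes to the fitted feature set (absent genes are zero
#' filled), normalizes, transforms, standardizes, and projects.  By default
#' query features are standardized with the *reference* means and standard
#' deviations (folding-in), which mitigates batch effects by projecting
#' queries into the subspace of reference variability.  Setting
#' `query_stats = TRUE` standardizes with statistics estimated from the
#' query cells themselves, the mode used when reference and query come from
#' different species and share only homologous features.
#'
#' @param P a fitted `Preprocessor`.
#' @param Q query [expression_matrix()].
#' @param query_stats logical; standardize with query-side statistics
#'   (default `FALSE`).
#' @return D x N' real matrix of reduced query profiles.
#' @export
apply_preprocessor <- function(P, Q, query_stats = FALSE) {
  A <- align_genes(Q, P$selected_genes)
  Y <- normalize_cells(A$counts, P$config$scale_factor, A$cell_names)
  Z <- transform_counts(Y, P$config$transform)
  if (query_stats && ncol(Z) >= 2L) {
    mu <- rowMeans(Z)
    sds <- apply(Z, 1L, sd)
    sds[sds < 1e-8] <- 1
  } else {
    mu <- P$feature_means
    sds <- P$feature_sds
  }
  Zs <- (Z - mu) / sds
  out <- P$projection %*% Zs
  colnames(out) <- A$cell_names
  out
}
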