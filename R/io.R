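#' Construct an expression matrix of UMI counts
#'
#' A light container for a digital gene expression (DGE) matrix: non-negative
#' integer counts with genes in rows and cells in columns, plus unique gene
#' and cell names.  Counts may be dense or a `Matrix` sparse matrix.
#'
#' @param counts non-negative integer matrix (genes x cells), dense or sparse.
#' @param gene_names character vector of unique gene names (one per row).
#'   Surrounding whitespace is trimmed.
#' @param cell_names character vector of unique cell names (one per column).
#' @return An object of class `ExpressionMatrix` with elements `counts`,
#'   `gene_names`, `cell_names`.
#' @export
expression_matrix <- function(counts, gene_names, cell_names) {
  gene_names <- trimws(as.character(gene_names))
  cell_names <- as.character(cell_names)
  if (nrow(counts) != length(gene_names))
    stopf("counts has %d rows but %d gene names", nrow(counts), length(gene_names))
  if (ncol(counts) != length(cell_names))
    stopf("counts has %d columns but %d cell names", ncol(counts), length(cell_names))
  if (anyDuplicated(gene_names))
    stopf("duplicate gene names (e.g. '%s')", gene_names[duplicated(gene_names)][1L])
  if (anyDuplicated(cell_names))
    stopf("duplicate cell names (e.g. '%s')", cell_names[duplicated(cell_names)][1L])
  vals <- if (is(counts, "sparseMatrix")) counts@x else counts
  if (length(vals) && min(vals) < 0) stop("counts contain negative entries")
  if (length(vals) && any(vals != floor(vals))) {
    bad <- which(vals != floor(vals))[1L]
    stopf("non-integer count entry detected (value %g)", vals[bad])
  }
  dimnames(counts) <- NULL
  structure(list(counts = counts, gene_names = gene_names, cell_names = cell_names),
            class = "ExpressionMatrix")
}

#' @method print ExpressionMatrix
#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells (%s)\n",
              length(x$gene_names), length(x$cell_names),
              if (is(x$counts, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

#' @method dim ExpressionMatrix
#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

guess_format <- function(path) {
  p <- sub("\\.gz$", "", path)
  ext <- tolower(tools::file_ext(p))
  switch(ext,
         mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
         stopf("cannot guess DGE format from extension '.%s'", ext))
}

find_sidecar <- function(dir, stems) {
  for (stem in stems) {
    for (ext in c(".tsv", ".txt", ".tsv.gz", ".txt.gz")) {
      p <- file.path(dir, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
  }
  NULL
}

read_name_column <- function(path) {
  tab <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character")
  tab[[1L]]
}

#' Read a digital gene expression matrix
#'
#' Reads UMI counts from MatrixMarket (`.mtx` with `genes.tsv`/`features.tsv`
#' and `barcodes.tsv` sidecars in the same directory) or delimited text
#' (genes in rows, cells in columns, gene names in the first column, cell
#' names in the header).  Gzip-compressed files are accepted.  The returned
#' matrix is always genes x cells; for MatrixMarket input the on-disk
#' orientation is resolved by matching sidecar lengths to the matrix
#' dimensions.
#'
#' @param path path to the matrix file.
#' @param format one of `"auto"` (default; by extension), `"mtx"`, `"csv"`,
#'   `"tsv"`.
#' @return An [expression_matrix()].
#' @export
read_dge <- function(path, format = c("auto", "mtx", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") format <- guess_format(path)
  if (format == "mtx") {
    m <- Matrix::readMM(path)
    dir <- dirname(path)
    genes_path <- find_sidecar(dir, c("genes", "features"))
    cells_path <- find_sidecar(dir, c("barcodes", "cells"))
    if (is.null(genes_path) || is.null(cells_path))
      stopf("missing genes/features or barcodes sidecar next to %s", path)
    genes <- read_name_column(genes_path)
    cells <- read_name_column(cells_path)
    if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
      if (nrow(m) == ncol(m) && length(genes) == length(cells))
        stop("ambiguous orientation: square matrix with equal-length sidecars")
    } else if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
      m <- Matrix::t(m)
    } else {
      stopf("matrix is %d x %d but sidecars have %d genes and %d cells",
            nrow(m), ncol(m), length(genes), length(cells))
    }
    m <- as(m, "CsparseMatrix")
    expression_matrix(m, genes, cells)
  } else {
    sep <- if (format == "csv") "," else "\t"
    tab <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    genes <- trimws(as.character(tab[[1L]]))
    counts <- as.matrix(tab[, -1L, drop = FALSE])
    cells <- colnames(counts)
    storage.mode(counts) <- "double"
    expression_matrix(counts, genes, cells)
  }
}

#' Write a digital gene expression matrix
#'
#' Inverse of [read_dge()]: writes MatrixMarket (with `genes.tsv` and
#' `barcodes.tsv` sidecars) or delimited text.
#'
#' @param x an [expression_matrix()].
#' @param path output path for the matrix file.
#' @param format `"mtx"`, `"csv"`, or `"tsv"` (default `"auto"`, by extension).
#' @return `path`, invisibly.
#' @export
write_dge <- function(x, path, format = c("auto", "mtx", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "mtx") {
    m <- as(as(Matrix::Matrix(x$counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
    Matrix::writeMM(m, path)
    dir <- dirname(path)
    writeLines(x$gene_names, file.path(dir, "genes.tsv"))
    writeLines(x$cell_names, file.path(dir, "barcodes.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    counts <- as.matrix(x$counts)
    tab <- cbind(gene = x$gene_names, as.data.frame(counts))
    colnames(tab) <- c("gene", x$cell_names)
    write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Align query genes to a reference feature set
#'
#' Reorders the rows of a query matrix to match `reference_genes` exactly
#' (by trimmed string match).  Query genes absent from the reference are
#' dropped; reference genes absent from the query are filled with zero
#' counts.  A report of dropped/filled gene counts is attached as the
#' `"alignment"` attribute.
#'
#' @param query an [expression_matrix()].
#' @param reference_genes character vector of unique reference gene names.
#' @return An `ExpressionMatrix` with rows exactly `reference_genes`, in
#'   order, with attribute `alignment = list(n_shared, n_dropped, n_filled)`.
#' @export
align_genes <- function(query, reference_genes) {
  reference_genes <- trimws(as.character(reference_genes))
  if (anyDuplicated(reference_genes)) stop("reference_genes must be unique")
  idx <- match(reference_genes, query$gene_names)
  n_shared <- sum(!is.na(idx))
  if (n_shared == 0L) stop("query and reference share no gene names")
  nq <- length(query$cell_names)
  sparse <- is(query$counts, "sparseMatrix")
  if (sparse) {
    out <- Matrix::Matrix(0, length(reference_genes), nq, sparse = TRUE)
    out <- as(out, "CsparseMatrix")
  } else {
    out <- matrix(0, length(reference_genes), nq)
  }
  hit <- !is.na(idx)
  out[hit, ] <- query$counts[idx[hit], , drop = FALSE]
  res <- expression_matrix(out, reference_genes, query$cell_names)
  attr(res, "alignment") <- list(
    n_shared = n_shared,
    n_dropped = length(query$gene_names) - n_shared,
    n_filled = length(reference_genes) - n_shared
  )
  res
}
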