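#' Randomized truncated singular value decomposition
#'
#' Halko-style randomized SVD: a Gaussian range finder with oversampling,
#' power iterations with QR re-orthonormalization at each pass, and an exact
#' SVD of the small projected matrix, truncated to rank `D`.  Deterministic
#' given `rng_seed`.
#'
#' The optional `row_offset` supports implicit centering: the decomposition
#' is computed for `A - row_offset %*% t(rep(1, ncol(A)))` without ever
#' materializing the centered (dense) matrix, so sparse inputs stay sparse.
#'
#' @param A numeric matrix (dense or `Matrix` sparse), M x N.
#' @param D target rank, `D <= min(M, N)`.
#' @param n_oversamples extra columns in the test matrix (default 10).
#' @param n_power_iters number of subspace/power iterations (default 3).
#' @param rng_seed integer seed for the Gaussian test matrix.
#' @param row_offset optional numeric vector of length M subtracted from
#'   every column of `A` implicitly.
#' @return A list of class `SVDResult` with `U` (M x D), `S` (length D,
#'   non-increasing), `V` (N x D).
#' @export
randomized_svd <- function(A, D, n_oversamples = 10L, n_power_iters = 3L,
                           rng_seed = 0L, row_offset = NULL) {
  M <- nrow(A); N <- ncol(A)
  if (D > min(M, N)) stopf("rank D=%d exceeds min(dim(A)) = %d", D, min(M, N))
  if (D < 1L) stop("D must be >= 1")
  has_off <- !is.null(row_offset)
  if (has_off && length(row_offset) != M)
    stop("row_offset length must equal nrow(A)")
  ell <- min(D + n_oversamples, min(M, N))

  # centered products without materializing A - c 1^T
  mult <- function(X) {          # (A - c 1^T) X
    Y <- as.matrix(A %*% X)
    if (has_off) Y <- Y - outer(row_offset, colSums(X))
    Y
  }
  tmult <- function(Y) {         # (A - c 1^T)^T Y
    Z <- as.matrix(Matrix::crossprod(A, Y))
    if (has_off) Z <- Z - matrix(1, N, 1) %*% crossprod(row_offset, Y)
    Z
  }

  Omega <- with_seed(rng_seed, matrix(rnorm(N * ell), N, ell))
  Y <- mult(Omega)
  Q <- qr.Q(qr(Y))
  for (it in seq_len(n_power_iters)) {
    Z <- qr.Q(qr(tmult(Q)))
    Q <- qr.Q(qr(mult(Z)))
  }
  B <- t(tmult(Q))               # ell x N
  sv <- svd(B)
  keep <- seq_len(D)
  res <- list(U = Q %*% sv$u[, keep, drop = FALSE],
              S = sv$d[keep],
              V = sv$v[, keep, drop = FALSE])
  class(res) <- "SVDResult"
  res
}

#' @method print SVDResult
#' @export
print.SVDResult <- function(x, ...) {
  cat(sprintf("SVDResult: rank %d, singular values %s...\n",
              length(x$S), paste(signif(head(x$S, 3), 4), collapse = ", ")))
  invisible(x)
}
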