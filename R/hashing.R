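#' Generate (orthogonalized) random hyperplanes for SRP-LSH
#'
#' Draws `T` hyperplane normal vectors of length `D` from the standard
#' isotropic Gaussian.  With `orthogonalize = TRUE` the normals are processed
#' in `ceiling(T / D)` batches of at most `D` vectors; each batch is
#' orthonormalized by QR decomposition (with the sign convention that makes
#' the result the Gram-Schmidt orthonormalization of the draws, preserving
#' the Haar distribution of the spanned frame).  Orthogonalization removes
#' linear dependency among hyperplanes, which reduces the variance of the
#' angle estimator without biasing it.
#'
#' @param D dimension of the hashed space.
#' @param n_bits number of hyperplanes T (= bits per code).
#' @param orthogonalize logical (default `TRUE`).
#' @param rng_seed integer seed; the same seed reproduces the same normals.
#' @return A list of class `HyperplaneSet` with `normals` (T x D matrix,
#'   row i the normal of hyperplane i), `n_bits`, and `rng_seed`.
#' @export
generate_hyperplanes <- function(D, n_bits, orthogonalize = TRUE, rng_seed = 0L) {
  if (D < 1L || n_bits < 1L) stop("D and n_bits must be >= 1")
  normals <- with_seed(rng_seed, matrix(rnorm(n_bits * D), n_bits, D))
  if (orthogonalize) {
    start <- 1L
    while (start <= n_bits) {
      stop_ <- min(start + D - 1L, n_bits)
      B <- normals[start:stop_, , drop = FALSE]   # b x D, b <= D
      dec <- qr(t(B))
      Qm <- qr.Q(dec)
      signs <- sign(diag(qr.R(dec)))
      signs[signs == 0] <- 1
      normals[start:stop_, ] <- t(Qm * rep(signs, each = nrow(Qm)))
      start <- stop_ + 1L
    }
  }
  structure(list(normals = normals, n_bits = n_bits, rng_seed = rng_seed),
            class = "HyperplaneSet")
}

#' Encode reduced profiles as packed bit vectors
#'
#' Bit i of cell j is 1 iff the projection of column j onto hyperplane i is
#' strictly positive (an exactly zero projection maps to 0, fixed for
#' determinism).  Bits are packed little-endian within bytes; bit i of the
#' code corresponds to hyperplane i.
#'
#' @param X D x N real matrix of reduced profiles (columns are cells).
#' @param H a [generate_hyperplanes()] `HyperplaneSet` with matching D.
#' @return A list of class `BitCodes` with `codes` (raw matrix,
#'   `ceiling(T/8)` byte rows x N columns) and `n_bits`.
#' @export
encode_cells <- function(X, H) {
  if (nrow(X) != ncol(H$normals))
    stopf("X has %d rows but hyperplanes expect %d dims", nrow(X), ncol(H$normals))
  S <- H$normals %*% X
  codes <- pack_bits_cpp(S > 0)
  structure(list(codes = codes, n_bits = H$n_bits), class = "BitCodes")
}

#' @method print BitCodes
#' @export
print.BitCodes <- function(x, ...) {
  cat(sprintf("BitCodes: %d cells x %d bits\n", ncol(x$codes), x$n_bits))
  invisible(x)
}

bitcodes <- function(codes, n_bits) {
  structure(list(codes = codes, n_bits = n_bits), class = "BitCodes")
}

#' Hamming distances between bit codes
#'
#' @param x a `BitCodes` object (the database side).
#' @param query a raw vector (one packed code) or a `BitCodes` object.
#' @return If `query` is a single code, an integer vector of length N;
#'   otherwise an N x N' integer matrix.
#' @export
hamming_distance <- function(x, query) {
  if (is.raw(query)) hamming_all_cpp(x$codes, query)
  else hamming_matrix_cpp(x$codes, query$codes)
}

#' Estimate the angle between two profiles from a Hamming distance
#'
#' Under signed random projections the collision probability of one bit is
#' `1 - theta / pi`, so the Hamming distance over `T_total` independent bits
#' estimates the angle as `pi * d_H / T_total`.
#'
#' @param d_H Hamming distance(s), in `[0, T_total]`.
#' @param T_total number of bits compared (use `T * L` for distances summed
#'   over L hash indexes).
#' @return Angle estimate(s) in radians.
#' @export
estimate_angle <- function(d_H, T_total) {
  if (any(d_H < 0) || any(d_H > T_total)) stop("Hamming distance out of range")
  pi * d_H / T_total
}

#' Estimate cosine similarity from a Hamming distance
#'
#' `cos(estimate_angle(d_H, T_total))`; ranges from 1 (identical codes) to
#' -1 (complementary codes).
#'
#' @inheritParams estimate_angle
#' @return Cosine similarity estimate(s) in `[-1, 1]`.
#' @export
cosine_from_hamming <- function(d_H, T_total) {
  cos(estimate_angle(d_H, T_total))
}
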