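#' Build a multi-index hash over packed bit codes
#'
#' Splits each T-bit code into `ceiling(T / s)` blocks of `s` bits (the last
#' block may be shorter) and builds one direct-address subindex per block.
#' Each subindex is the filled/offsets/buckets triple: a bit vector marking
#' occupied subcode values (supporting ranked popcount lookup), offsets
#' delimiting bucket extents, and a flat array of database positions.
#' Lookup of a subcode returns exactly the database positions sharing that
#' subcode at that block.
#'
#' @param codes a `BitCodes` object (database cells).
#' @param s subcode length in bits, `1 <= s <= min(T, 24)`.  The default
#'   `clamp(floor(log2(max(N, 2))), 8, 16)` follows the usual multi-index
#'   hashing guidance that `s` near `log2(N)` balances bucket occupancy,
#'   capped so each subindex table has at most 2^16 entries.
#' @return A list of class `MultiIndexHash` with `codes`, `n_bits`, `s`,
#'   and `blocks`.
#' @export
build_mih <- function(codes, s = NULL) {
  T_bits <- codes$n_bits
  N <- ncol(codes$codes)
  if (is.null(s)) {
    s <- max(8L, min(16L, as.integer(floor(log2(max(N, 2))))))
    s <- min(s, T_bits)
  }
  s <- as.integer(s)
  if (s < 1L || s > min(T_bits, 24L)) stop("subcode length s out of range")
  blocks <- mih_build_cpp(codes$codes, T_bits, s)
  structure(list(codes = codes, n_bits = T_bits, s = s, blocks = blocks),
            class = "MultiIndexHash")
}

#' @method print MultiIndexHash
#' @export
print.MultiIndexHash <- function(x, ...) {
  cat(sprintf("MultiIndexHash: %d cells x %d bits, %d blocks of <= %d bits\n",
              ncol(x$codes$codes), x$n_bits, length(x$blocks), x$s))
  invisible(x)
}

#' Exact k-nearest-neighbor search in Hamming space
#'
#' Progressive radius expansion over the subindexes: at radius r all
#' subcodes within r bit flips of each query block are probed, candidates
#' are verified with full Hamming distances, and the search stops once the
#' current k-th best distance beats the generalized pigeonhole bound
#' `m * (r + 1)` (any unseen vector must then be strictly farther).  The
#' result is identical to a brute-force linear scan; ties at equal distance
#' are resolved by ascending database position.
#'
#' @param index a [build_mih()] `MultiIndexHash`.
#' @param query a raw vector (one packed code) or a `BitCodes` object with
#'   the same number of bits.
#' @param k number of neighbors (k >= 1; capped at the index size).
#' @return A list with `positions` and `distances`, each a
#'   `min(k, N)` x n_queries integer matrix, distance-sorted per column.
#' @export
knn_search <- function(index, query, k) {
  if (k < 1L) stop("k must be >= 1")
  qcodes <- if (is.raw(query)) matrix(query, ncol = 1L) else query$codes
  if (nrow(qcodes) != nrow(index$codes$codes))
    stop("query code length does not match the index")
  mih_knn_cpp(index$codes$codes, index$n_bits, index$blocks, qcodes,
              as.integer(k))
}

#' Size of the single-table Hamming search space
#'
#' Number of table buckets probed when scanning all codes within `r` bit
#' flips of a T-bit query in one direct-address table:
#' `sum_{i=0..r} choose(T, i)`.  The rapid growth of this count is the
#' motivation for splitting codes into blocks.
#'
#' @param n_bits code length T.
#' @param r search radius, `0 <= r <= n_bits`.
#' @return The exact count as a double (exact while below 2^53).
#' @export
search_space_size <- function(n_bits, r) {
  if (r < 0 || r > n_bits) stop("radius out of range")
  sum(choose(n_bits, 0:r))
}
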