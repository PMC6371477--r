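# Shared fixtures, built in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small clustered dataset used by several files
small_clustered <- function() {
  cached("small_clustered", make_dataset(
    synth_spec(n_genes = 600, n_cells = 150, n_clusters = 3,
               marker_genes_per_cluster = 60, seed = 101)))
}

# tiny deterministic count matrix
tiny_matrix <- function() {
  counts <- matrix(c(0, 1, 5, 9,
                     2, 0, 7, 3,
                     1, 1, 0, 4), nrow = 4)
  expression_matrix(counts, paste0("g", 1:4), paste0("c", 1:3))
}

# random packed codes: N cells hashed from random D-vectors
random_codes <- function(n_cells, n_bits, seed, D = 25) {
  X <- with_seed(seed, matrix(rnorm(D * n_cells), D, n_cells))
  H <- generate_hyperplanes(D, n_bits, orthogonalize = FALSE, rng_seed = seed + 1L)
  encode_cells(X, H)
}

with_seed <- cellhash:::with_seed

# truncate packed codes to the first n bits
bitcodes_trim <- function(bc, n_bits) {
  bits <- cellhash:::unpack_bits_cpp(bc$codes, bc$n_bits)[seq_len(n_bits), , drop = FALSE]
  structure(list(codes = cellhash:::pack_bits_cpp(bits), n_bits = n_bits),
            class = "BitCodes")
}

# brute-force k-NN oracle over packed codes
brute_knn <- function(codes, query, k) {
  d <- cellhash:::hamming_all_cpp(codes$codes, query)
  ord <- order(d, seq_along(d))[seq_len(min(k, length(d)))]
  list(positions = ord, distances = d[ord])
}

# R-side subindex lookup straight from the filled/offsets/buckets arrays
lookup_subcode <- function(block, value) {
  byte <- as.integer(block$filled[value %/% 8L + 1L])
  bit <- value %% 8L
  if (bitwAnd(byte, bitwShiftL(1L, bit)) == 0L) return(integer(0))
  filled_bits <- function(b) sum(bitwAnd(b, bitwShiftL(1L, 0:7)) != 0L)
  full_bytes <- as.integer(block$filled)[seq_len(value %/% 8L)]
  rank <- sum(vapply(full_bytes, filled_bits, 1L)) +
    sum(bitwAnd(byte, bitwShiftL(1L, seq_len(bit) - 1L)) != 0L)
  block$buckets[(block$offsets[rank + 1L] + 1L):block$offsets[rank + 2L]] + 1L
}

# subcode of cell j at a block, from unpacked bits
subcode_of <- function(bits, block, j) {
  idx <- block$bit_lo + seq_len(block$nbits)
  sum(bits[idx, j] * 2 ^ (seq_len(block$nbits) - 1L))
}
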