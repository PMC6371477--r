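# Single-file database container (".ch").
#
# Layout (all integers little-endian):
#   bytes 0-3   magic "CHDB"
#   int32       container format version (currently 1)
#   int32       number of sections
#   per section:
#     int32     name length, then name bytes (ASCII)
#     float64   payload length in bytes
#     float64   CRC-32 of the payload
#     payload   R serialization (version 3) of the section object
#
# Per-cell count blocks inside the "raw_store" section stay gzip-compressed
# until decompress_cell() is called on them.

CH_MAGIC <- charToRaw("CHDB")
CH_VERSION <- 1L

write_section <- function(con, name, obj) {
  payload <- serialize(obj, NULL, version = 3L)
  nm <- charToRaw(name)
  writeBin(length(nm), con, size = 4L, endian = "little")
  writeBin(nm, con)
  writeBin(as.double(length(payload)), con, size = 8L, endian = "little")
  writeBin(crc32_cpp(payload), con, size = 8L, endian = "little")
  writeBin(payload, con)
}

read_section <- function(con) {
  nlen <- readBin(con, "integer", size = 4L, endian = "little")
  if (length(nlen) == 0L) stop("truncated database file: section table ends early")
  name <- rawToChar(readBin(con, "raw", n = nlen))
  plen <- readBin(con, "double", size = 8L, endian = "little")
  crc <- readBin(con, "double", size = 8L, endian = "little")
  payload <- readBin(con, "raw", n = plen)
  if (length(payload) < plen)
    stopf("truncated database file in section '%s'", name)
  if (crc32_cpp(payload) != crc)
    stopf("checksum mismatch in section '%s': file is corrupted", name)
  list(name = name, obj = unserialize(payload))
}

#' Save a cell database to a single file
#'
#' Writes a versioned, sectioned container with a CRC-32 checksum per
#' section.  Serialization is deterministic: saving the same database twice
#' produces byte-identical files.
#'
#' @param db a `CellDatabase`.
#' @param path output path (conventionally `.ch`).
#' @return `path`, invisibly.
#' @export
save_db <- function(db, path) {
  if (!inherits(db, "CellDatabase")) stop("db must be a CellDatabase")
  sections <- list(
    header = list(format_version = db$format_version, n_bits = db$n_bits,
                  n_lshashes = db$n_lshashes, build_seed = db$build_seed),
    preprocessor = unclass(db$preprocessor),
    hashes = db$hashes,
    metadata = db$metadata)
  if (!is.null(db$raw_store)) sections$raw_store <- unclass(db$raw_store)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(CH_MAGIC, con)
  writeBin(CH_VERSION, con, size = 4L, endian = "little")
  writeBin(length(sections), con, size = 4L, endian = "little")
  for (nm in names(sections)) write_section(con, nm, sections[[nm]])
  invisible(path)
}

#' Load a cell database from a file
#'
#' Verifies the magic bytes, container version, and per-section checksums,
#' then reassembles a ready-to-query `CellDatabase`.  Compressed raw counts
#' (if present) are kept compressed; cells are decompressed only on request.
#'
#' @param path path to a file written by [save_db()].
#' @return A `CellDatabase`.
#' @export
load_db <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (!identical(magic, CH_MAGIC)) stop("not a cellhash database file (bad magic)")
  ver <- readBin(con, "integer", size = 4L, endian = "little")
  if (!identical(ver, CH_VERSION))
    stopf("unsupported container version %d (this build reads version %d)",
          ver, CH_VERSION)
  nsec <- readBin(con, "integer", size = 4L, endian = "little")
  sections <- list()
  for (i in seq_len(nsec)) {
    s <- read_section(con)
    sections[[s$name]] <- s$obj
  }
  for (required in c("header", "preprocessor", "hashes", "metadata"))
    if (is.null(sections[[required]]))
      stopf("database file is missing the '%s' section", required)
  hd <- sections$header
  P <- sections$preprocessor
  class(P) <- "Preprocessor"
  raw_store <- sections$raw_store
  if (!is.null(raw_store)) class(raw_store) <- "CompressedCounts"
  structure(list(preprocessor = P, hashes = sections$hashes,
                 metadata = sections$metadata, raw_store = raw_store,
                 n_bits = hd$n_bits, n_lshashes = hd$n_lshashes,
                 build_seed = hd$build_seed,
                 format_version = hd$format_version),
            class = "CellDatabase")
}

#' Describe a saved database
#'
#' @param path path to a `.ch` file.
#' @return Invisibly, a list with N, n_features, D, T, L, has_counts;
#'   printed as a short report.
#' @export
db_info <- function(path) {
  db <- load_db(path)
  info <- list(N = nrow(db$metadata),
               n_features = length(db$preprocessor$selected_genes),
               D = nrow(db$preprocessor$projection),
               T = db$n_bits, L = db$n_lshashes,
               has_counts = !is.null(db$raw_store))
  cat(sprintf("cells: %d\nfeatures: %d\nD: %d\nT: %d\nL: %d\nraw counts: %s\n",
              info$N, info$n_features, info$D, info$T, info$L,
              if (info$has_counts) "yes" else "no"))
  invisible(info)
}
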