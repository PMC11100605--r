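# Minimal baseline-TIFF reader/writer for uncompressed grayscale images.
#
# No TIFF package is available in the target library set, so the package
# carries its own implementation of the small corner of the format it needs:
# single-sample (grayscale) pages, no compression, 8/16-bit unsigned or
# 32/64-bit IEEE float samples, one or more strips, multi-page. The writer
# always emits little-endian single-strip pages; the reader accepts both
# byte orders. This is sufficient for microscope exports converted to plain
# TIFF and for everything the simulator writes.

TIFF_TYPE_SIZES <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

rd_int <- function(raw, off, size, endian, signed = TRUE) {
  readBin(raw[(off + 1L):(off + size)], "integer", n = 1L, size = size,
          endian = endian, signed = signed)
}

rd_u32 <- function(raw, off, endian) {
  v <- rd_int(raw, off, 4L, endian, signed = TRUE)
  if (v < 0) v <- v + 2^32
  v
}

# read `count` values of a given TIFF type from an IFD entry's value field
# (inline if they fit in 4 bytes, else at the pointed-to offset)
rd_values <- function(raw, entry_off, type, count, endian) {
  size <- TIFF_TYPE_SIZES[type]
  total <- size * count
  off <- if (total <= 4L) entry_off + 8L else rd_u32(raw, entry_off + 8L, endian)
  vapply(seq_len(count), function(k) {
    o <- off + (k - 1L) * size
    if (size == 2L) rd_int(raw, o, 2L, endian, signed = FALSE)
    else if (size == 4L) rd_u32(raw, o, endian)
    else as.numeric(raw[o + 1L])
  }, numeric(1))
}

#' Read an uncompressed grayscale TIFF
#'
#' Supports multi-page files, 8/16-bit unsigned and 32/64-bit float samples,
#' little- or big-endian, one or more strips per page. Compressed, tiled,
#' or multi-sample (e.g. RGB) files are rejected with an informative error.
#'
#' @param path file path.
#' @return a list of numeric matrices, one per page (row 1 = top image row).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  byte_order <- rawToChar(raw[1:2])
  endian <- switch(byte_order, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  if (rd_int(raw, 2L, 2L, endian, signed = FALSE) != 42L)
    stop("not a TIFF file (bad magic): ", path)

  pages <- list()
  ifd_off <- rd_u32(raw, 4L, endian)
  while (ifd_off != 0) {
    n_entries <- rd_int(raw, ifd_off, 2L, endian, signed = FALSE)
    tags <- list()
    for (e in seq_len(n_entries)) {
      eoff <- ifd_off + 2L + (e - 1L) * 12L
      tag <- rd_int(raw, eoff, 2L, endian, signed = FALSE)
      type <- rd_int(raw, eoff + 2L, 2L, endian, signed = FALSE)
      count <- rd_u32(raw, eoff + 4L, endian)
      if (type >= 1L && type <= 12L)
        tags[[as.character(tag)]] <- rd_values(raw, eoff, type, count, endian)
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    width <- g(256); height <- g(257)
    if (is.null(width) || is.null(height)) stop("TIFF page missing dimensions")
    bits <- g(258, 1)[1L]
    if (g(259, 1)[1L] != 1) stop("compressed TIFF not supported")
    if (g(277, 1)[1L] != 1) stop("only single-sample (grayscale) TIFF supported")
    sfmt <- g(339, 1)[1L]
    strip_off <- g(273); strip_cnt <- g(279)
    if (is.null(strip_off)) stop("TIFF page missing strip offsets")
    if (is.null(strip_cnt)) {
      if (length(strip_off) != 1L) stop("TIFF page missing strip byte counts")
      strip_cnt <- height * width * bits / 8
    }
    data_raw <- raw[unlist(lapply(seq_along(strip_off), function(k)
      (strip_off[k] + 1L):(strip_off[k] + strip_cnt[k])))]
    npx <- width * height
    vals <- if (sfmt == 3) {
      readBin(data_raw, "double", n = npx, size = bits / 8, endian = endian)
    } else if (bits == 8L) {
      as.numeric(data_raw[seq_len(npx)])
    } else if (bits == 16L) {
      as.numeric(readBin(data_raw, "integer", n = npx, size = 2L,
                         endian = endian, signed = FALSE))
    } else if (bits == 32L) {
      v <- readBin(data_raw, "integer", n = npx, size = 4L, endian = endian)
      v <- as.numeric(v); v[v < 0] <- v[v < 0] + 2^32; v
    } else stop("unsupported TIFF sample layout: ", bits, "-bit, format ", sfmt)
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = height, byrow = TRUE)
    ifd_off <- rd_u32(raw, ifd_off + 2L + n_entries * 12L, endian)
  }
  pages
}

wr_u16 <- function(con, v) {
  v <- as.integer(round(v))
  v[v > 32767L] <- v[v > 32767L] - 65536L
  writeBin(v, con, size = 2L, endian = "little")
}
wr_u32 <- function(con, v) {
  v <- round(v)
  v[v > 2^31 - 1] <- v[v > 2^31 - 1] - 2^32
  writeBin(as.integer(v), con, size = 4L, endian = "little")
}

#' Write matrices as an uncompressed multi-page grayscale TIFF
#'
#' @param pages a matrix or list of numeric matrices.
#' @param path output file path.
#' @param type `"float64"` (lossless for R numerics; default), `"float32"`,
#'   or `"uint16"` (values must be integers in 0..65535, e.g. label masks).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path, type = c("float64", "float32", "uint16")) {
  type <- match.arg(type)
  if (is.matrix(pages)) pages <- list(pages)
  if (!length(pages)) stop("no pages to write")
  bits <- switch(type, float64 = 64L, float32 = 32L, uint16 = 16L)
  sfmt <- if (type == "uint16") 1L else 3L
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L

  sizes <- vapply(pages, function(m) length(m) * bits / 8, numeric(1))
  data_off <- 8 + cumsum(c(0, sizes[-length(sizes)]))
  ifd_start <- 8 + sum(sizes)
  ifd_off <- ifd_start + (seq_along(pages) - 1) * ifd_size

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  wr_u16(con, 42L)
  wr_u32(con, ifd_off[1L])
  for (p in seq_along(pages)) {
    v <- as.vector(t(pages[[p]]))  # TIFF strips are row-major
    if (type == "uint16") {
      if (any(v < 0 | v > 65535 | v != round(v)))
        stop("uint16 TIFF requires integer values in 0..65535")
      wr_u16(con, v)
    } else {
      writeBin(as.numeric(v), con, size = bits / 8, endian = "little")
    }
  }
  entry <- function(tag, type_id, value) {
    wr_u16(con, tag); wr_u16(con, type_id); wr_u32(con, 1L)
    if (type_id == 3L) { wr_u16(con, value); wr_u16(con, 0L) }
    else wr_u32(con, value)
  }
  for (p in seq_along(pages)) {
    m <- pages[[p]]
    wr_u16(con, n_entries)
    entry(256L, 4L, ncol(m))          # ImageWidth
    entry(257L, 4L, nrow(m))          # ImageLength
    entry(258L, 3L, bits)             # BitsPerSample
    entry(259L, 3L, 1L)               # Compression = none
    entry(262L, 3L, 1L)               # Photometric = BlackIsZero
    entry(273L, 4L, data_off[p])      # StripOffsets
    entry(277L, 3L, 1L)               # SamplesPerPixel
    entry(278L, 4L, nrow(m))          # RowsPerStrip
    entry(279L, 4L, sizes[p])         # StripByteCounts
    entry(339L, 3L, sfmt)             # SampleFormat
    wr_u32(con, if (p < length(pages)) ifd_off[p + 1L] else 0L)
  }
  invisible(path)
}
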