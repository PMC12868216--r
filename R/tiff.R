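# Minimal single-page grayscale TIFF codec.
#
# Scope: uncompressed, one sample per pixel, 8/16-bit unsigned integer or
# 32-bit IEEE float, striped layout. Reads both little- and big-endian
# files; always writes little-endian, single strip. This covers the TIFF
# dialect produced by common micro-CT reconstruction exports and by
# Python's tifffile for 2D grayscale data.

.tiff_tags <- c(
  width = 256L, length = 257L, bits = 258L, compression = 259L,
  photometric = 262L, strip_offsets = 273L, spp = 277L,
  rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L
)

# type sizes indexed by TIFF field type code
.tiff_type_size <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

.read_uint <- function(raw, offset, size, endian) {
  # offset is 0-based; returns double (values may exceed .Machine$integer.max)
  bytes <- as.integer(raw[(offset + 1L):(offset + size)])
  if (endian == "big") bytes <- rev(bytes)
  sum(bytes * 256^(seq_len(size) - 1L))
}

.read_ifd_values <- function(raw, type, count, value_field, endian) {
  size <- .tiff_type_size[type]
  total <- size * count
  if (total <= 4L) {
    src <- value_field
  } else {
    off <- .read_uint(value_field, 0L, 4L, endian)
    src <- raw[(off + 1L):(off + total)]
  }
  vapply(seq_len(count), function(i) {
    .read_uint(src, (i - 1L) * size, size, endian)
  }, numeric(1))
}

read_tiff_slice <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file (too short): ", path)
  byte_order <- rawToChar(raw[1:2])
  endian <- switch(byte_order, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  magic <- .read_uint(raw, 2L, 2L, endian)
  if (magic != 42) stop("not a TIFF file (bad magic number): ", path)
  ifd_off <- .read_uint(raw, 4L, 4L, endian)
  n_entries <- .read_uint(raw, ifd_off, 2L, endian)
  tags <- list()
  for (i in seq_len(n_entries)) {
    base <- ifd_off + 2L + (i - 1L) * 12L
    tag <- .read_uint(raw, base, 2L, endian)
    type <- .read_uint(raw, base + 2L, 2L, endian)
    count <- .read_uint(raw, base + 4L, 4L, endian)
    value_field <- raw[(base + 9L):(base + 12L)]
    tags[[as.character(tag)]] <- .read_ifd_values(raw, type, count,
                                                  value_field, endian)
  }
  g <- function(tag, default = NULL) {
    v <- tags[[as.character(.tiff_tags[[tag]])]]
    if (is.null(v)) default else v
  }
  width <- g("width"); height <- g("length")
  if (is.null(width) || is.null(height)) stop("TIFF missing dimensions: ", path)
  if (g("compression", 1) != 1) {
    stop("unsupported TIFF (compressed): ", path)
  }
  if (g("spp", 1) != 1) stop("unsupported TIFF (multi-sample): ", path)
  bits <- g("bits", 1)
  fmt <- g("sample_format", 1)
  if (!((bits %in% c(8, 16) && fmt == 1) || (bits == 32 && fmt == 3))) {
    stop("unsupported TIFF sample layout (bits=", bits, ", format=", fmt,
         "): ", path)
  }
  offsets <- g("strip_offsets")
  counts <- g("strip_bytes", width * height * bits / 8)
  data_raw <- raw(0)
  for (i in seq_along(offsets)) {
    data_raw <- c(data_raw, raw[(offsets[i] + 1L):(offsets[i] + counts[i])])
  }
  n_px <- width * height
  values <- if (bits == 8) {
    as.numeric(readBin(data_raw, "integer", n = n_px, size = 1L,
                       signed = FALSE, endian = endian))
  } else if (bits == 16) {
    as.numeric(readBin(data_raw, "integer", n = n_px, size = 2L,
                       signed = FALSE, endian = endian))
  } else {
    readBin(data_raw, "numeric", n = n_px, size = 4L, endian = endian)
  }
  list(
    pixels = matrix(values, nrow = height, ncol = width, byrow = TRUE),
    bits = as.integer(bits),
    format = if (fmt == 3) "float" else "uint"
  )
}

.uint_bytes <- function(values, size) {
  # little-endian encoding of non-negative integers as raw
  out <- raw(size * length(values))
  v <- values
  for (b in seq_len(size)) {
    out[seq(b, by = size, length.out = length(values))] <-
      as.raw(v %% 256)
    v <- v %/% 256
  }
  out
}

.ifd_entry <- function(tag, type, count, value_bytes) {
  pad <- raw(4L - length(value_bytes))
  c(.uint_bytes(tag, 2L), .uint_bytes(type, 2L), .uint_bytes(count, 4L),
    value_bytes, pad)
}

write_tiff_slice <- function(pixels, path, bits, float = FALSE) {
  stopifnot(is.matrix(pixels))
  height <- nrow(pixels); width <- ncol(pixels)
  byte_size <- bits / 8L
  n_entries <- 10L
  ifd_bytes <- 2L + n_entries * 12L + 4L
  data_offset <- 8L + ifd_bytes
  data_bytes <- width * height * byte_size
  long <- function(tag, v) .ifd_entry(tag, 4L, 1L, .uint_bytes(v, 4L))
  short <- function(tag, v) .ifd_entry(tag, 3L, 1L, .uint_bytes(v, 2L))
  entries <- c(
    long(.tiff_tags[["width"]], width),
    long(.tiff_tags[["length"]], height),
    short(.tiff_tags[["bits"]], bits),
    short(.tiff_tags[["compression"]], 1L),
    short(.tiff_tags[["photometric"]], 1L),
    long(.tiff_tags[["strip_offsets"]], data_offset),
    short(.tiff_tags[["spp"]], 1L),
    long(.tiff_tags[["rows_per_strip"]], height),
    long(.tiff_tags[["strip_bytes"]], data_bytes),
    short(.tiff_tags[["sample_format"]], if (float) 3L else 1L)
  )
  header <- c(charToRaw("II"), .uint_bytes(42L, 2L), .uint_bytes(8L, 4L))
  ifd <- c(.uint_bytes(n_entries, 2L), entries, .uint_bytes(0L, 4L))
  row_major <- as.vector(t(pixels))
  payload <- if (float) {
    writeBin(as.numeric(row_major), raw(), size = 4L, endian = "little")
  } else {
    .uint_bytes(round(row_major), byte_size)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, ifd, payload), con)
  invisible(path)
}
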