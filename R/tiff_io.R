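# Minimal baseline TIFF codec for uncompressed 32-bit float (and 16-bit
# unsigned) grayscale multi-page stacks, little-endian, one strip per
# page. Implemented here because the available TIFF bindings only store
# integer sample formats, which cannot round-trip floating-point image
# data losslessly; this writer emits standard SampleFormat=IEEEFP files
# that ImageJ/tifffile read directly.

tiff_types <- c(BYTE = 1L, SHORT = 3L, LONG = 4L)

# one 12-byte IFD entry with an inline (<= 4 byte) value
ifd_entry <- function(tag, type, value) {
  con <- raw(0)
  w2 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  val <- if (type == tiff_types["SHORT"]) c(w2(value), as.raw(c(0, 0))) else w4(value)
  c(w2(tag), w2(type), w4(1L), val)
}

#' Write a multi-page grayscale TIFF (float32 or uint16)
#'
#' Low-level writer used by [write_tiff_stack()]: uncompressed,
#' little-endian, one strip per page, `SampleFormat` 3 (IEEE float) or
#' 1 (unsigned integer). Float data round-trip bit-exactly for values
#' representable in 32-bit floats.
#'
#' @param pages List of numeric matrices (all the same size).
#' @param path Output file.
#' @param format `"float32"` or `"uint16"` (values must then be integers
#'   in 0..65535).
#' @return `path`, invisibly.
#' @export
tiff_write <- function(pages, path, format = c("float32", "uint16")) {
  format <- match.arg(format)
  if (!is.list(pages)) pages <- list(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  for (p in pages) if (nrow(p) != h || ncol(p) != w)
    stop("all pages must have identical dimensions")
  bps <- if (format == "float32") 32L else 16L
  sfmt <- if (format == "float32") 3L else 1L
  bytes_px <- bps / 8L
  strip_len <- h * w * bytes_px

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, size = 2, endian = "little")
  n <- length(pages)
  # layout: header(8) | page strips | IFDs
  strip_off <- 8 + (seq_len(n) - 1) * strip_len
  ifd_size <- 2 + 10 * 12 + 4
  ifd_off <- 8 + n * strip_len + (seq_len(n) - 1) * ifd_size
  writeBin(as.integer(ifd_off[1]), con, size = 4, endian = "little")
  for (p in pages) {
    v <- as.vector(t(p))  # TIFF is row-major
    if (format == "float32") {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      if (any(v < 0 | v > 65535 | v != round(v)))
        stop("uint16 pages must contain integers in 0..65535")
      # writeBin has no unsigned 16-bit; fold into signed range
      vi <- as.integer(v)
      vi[vi > 32767L] <- vi[vi > 32767L] - 65536L
      writeBin(vi, con, size = 2, endian = "little")
    }
  }
  for (i in seq_len(n)) {
    entries <- c(
      ifd_entry(256, tiff_types["LONG"], w),
      ifd_entry(257, tiff_types["LONG"], h),
      ifd_entry(258, tiff_types["SHORT"], bps),
      ifd_entry(259, tiff_types["SHORT"], 1L),       # no compression
      ifd_entry(262, tiff_types["SHORT"], 1L),       # black-is-zero
      ifd_entry(273, tiff_types["LONG"], strip_off[i]),
      ifd_entry(277, tiff_types["SHORT"], 1L),
      ifd_entry(278, tiff_types["LONG"], h),
      ifd_entry(279, tiff_types["LONG"], strip_len),
      ifd_entry(339, tiff_types["SHORT"], sfmt)
    )
    writeBin(as.integer(10L), con, size = 2, endian = "little")
    writeBin(entries, con)
    nxt <- if (i < n) ifd_off[i + 1] else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF written by [tiff_write()]
#'
#' Supports uncompressed single-sample little- or big-endian files with
#' float32 or unsigned 8/16-bit samples and any strip layout.
#'
#' @param path TIFF file.
#' @return List of numeric matrices.
#' @export
tiff_read <- function(path) {
  raw_all <- readBin(path, "raw", file.size(path))
  if (length(raw_all) < 8) stop("format error: file too short: ", path)
  endian <- if (rawToChar(raw_all[1:2]) == "II") "little"
            else if (rawToChar(raw_all[1:2]) == "MM") "big"
            else stop("format error: not a TIFF (bad byte order mark) in ", path)
  rd <- function(off, size, n = 1, what = "integer") {
    readBin(raw_all[(off + 1):(off + size * n)], what, n = n, size = size,
            endian = endian, signed = size > 2)
  }
  if (rd(2, 2) != 42) stop("format error: bad TIFF magic in ", path)
  ifd <- rd(4, 4)
  pages <- list()
  while (ifd != 0) {
    n_ent <- rd(ifd, 2)
    tags <- list()
    for (e in seq_len(n_ent)) {
      off <- ifd + 2 + (e - 1) * 12
      tag <- rd(off, 2); type <- rd(off + 2, 2); cnt <- rd(off + 4, 4)
      val <- if (type == 3 && cnt == 1) rd(off + 8, 2)
             else if (cnt == 1) rd(off + 8, 4)
             else {
               voff <- rd(off + 8, 4)
               rd(voff, if (type == 3) 2 else 4, cnt)
             }
      tags[[as.character(tag)]] <- val
    }
    g <- function(t, default = NULL) {
      v <- tags[[as.character(t)]]
      if (is.null(v)) default else v
    }
    w <- g(256); h <- g(257)
    bps <- g(258, 1L); comp <- g(259, 1L); sfmt <- g(339, 1L)
    if (is.null(w) || is.null(h)) stop("format error: missing dimensions in ", path)
    if (comp != 1) stop("format error: compressed TIFF not supported: ", path)
    offs <- g(273); cnts <- g(279, h * w * bps / 8)
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      npx <- cnts[s] / (bps / 8)
      vals <- c(vals, switch(as.character(bps),
        "32" = if (sfmt == 3) rd(offs[s], 4, npx, "numeric")
               else rd(offs[s], 4, npx),
        "16" = {
          v <- rd(offs[s], 2, npx)
          v[v < 0] <- v[v < 0] + 65536
          v
        },
        "8" = as.integer(raw_all[(offs[s] + 1):(offs[s] + npx)]),
        stop("format error: unsupported bit depth ", bps, " in ", path)))
    }
    pages[[length(pages) + 1]] <- matrix(vals, h, w, byrow = TRUE)
    ifd <- rd(ifd + 2 + n_ent * 12, 4)
  }
  pages
}
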