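# Minimal baseline TIFF support: uncompressed, grayscale, little-endian,
# one strip per page, 32-bit float (SampleFormat 3) or unsigned 8/16-bit
# integer pages, multi-page via chained IFDs, per-page ImageDescription.
# This covers exactly what the package writes; no external TIFF library is
# required at run time.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L,
               ImageDescription = 270L, StripOffsets = 273L,
               SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, SampleFormat = 339L)

#' Write matrices as a multi-page TIFF
#'
#' @param pages A matrix or list of equally sized matrices, one per page.
#' @param path Output file.
#' @param descriptions Character vector of per-page ImageDescription strings
#'   (e.g. page names or JSON metadata); recycled if length 1.
#' @param type `"float32"` (default) or `"uint16"` / `"uint8"` for label
#'   images.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path, descriptions = "", type = "float32") {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1L, all(vapply(pages, is.matrix, logical(1))))
  type <- match.arg(type, c("float32", "uint16", "uint8"))
  bps <- switch(type, float32 = 32L, uint16 = 16L, uint8 = 8L)
  fmt <- switch(type, float32 = 3L, 1L)
  descriptions <- rep_len(as.character(descriptions), length(pages))
  n <- length(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  if (!all(vapply(pages, function(p) all(dim(p) == c(h, w)), logical(1))))
    stop("all pages must share the same shape", call. = FALSE)
  desc_raw <- lapply(descriptions, function(d) {
    r <- c(charToRaw(d), as.raw(0))
    if (length(r) %% 2L) r <- c(r, as.raw(0))  # keep offsets even
    r
  })
  data_bytes <- as.integer(h) * w * (bps / 8L)
  if (data_bytes %% 2L) data_bytes <- data_bytes  # 8/even widths assumed
  ifd_bytes <- 2L + length(TIFF_TAGS) * 12L + 4L
  # layout: header | per page { data, desc, ifd }
  off <- 8L
  data_off <- desc_off <- ifd_off <- integer(n)
  for (i in seq_len(n)) {
    data_off[i] <- off; off <- off + data_bytes + (data_bytes %% 2L)
    desc_off[i] <- off; off <- off + length(desc_raw[[i]])
    ifd_off[i] <- off; off <- off + ifd_bytes
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2,
                              endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4,
                              endian = "little")
  writeBin(charToRaw("II"), con); wr2(42L); wr4(ifd_off[1])
  entry <- function(tag, typ, count, value) { # typ: 3 SHORT, 4 LONG, 2 ASCII
    wr2(tag); wr2(typ); wr4(count)
    if (typ == 3L) { wr2(value); wr2(0L) } else wr4(value)
  }
  for (i in seq_len(n)) {
    v <- as.vector(t(pages[[i]]))  # row-major
    if (type == "float32")
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    else
      writeBin(as.integer(v), con, size = bps / 8L, endian = "little")
    if (data_bytes %% 2L) writeBin(as.raw(0), con)
    writeBin(desc_raw[[i]], con)
    wr2(length(TIFF_TAGS))
    entry(256L, 4L, 1L, w)
    entry(257L, 4L, 1L, h)
    entry(258L, 3L, 1L, bps)
    entry(259L, 3L, 1L, 1L)            # no compression
    entry(262L, 3L, 1L, 1L)            # BlackIsZero
    entry(270L, 2L, length(desc_raw[[i]]), desc_off[i])
    entry(273L, 4L, 1L, data_off[i])
    entry(277L, 3L, 1L, 1L)
    entry(278L, 4L, 1L, h)
    entry(279L, 4L, 1L, data_bytes)
    entry(339L, 3L, 1L, fmt)
    wr4(if (i < n) ifd_off[i + 1] else 0L)
  }
  invisible(path)
}

#' Read a multi-page TIFF written by [write_tiff()]
#'
#' Supports the subset of baseline TIFF the package writes: little-endian,
#' uncompressed, grayscale, single strip per page.  Malformed or
#' unsupported files raise an error naming the file and the offending
#' field.
#'
#' @param path TIFF file path.
#' @return List with `pages` (list of matrices) and `descriptions`
#'   (character vector of per-page ImageDescription strings, `""` if
#'   absent).
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u2 <- function(at) sum(as.integer(raw[at + 0:1]) * c(1, 256))
  u4 <- function(at) sum(as.integer(raw[at + 0:3]) * 256^(0:3))
  bad <- function(field) stop(sprintf("malformed TIFF %s: %s", path, field),
                              call. = FALSE)
  if (length(raw) < 8 || rawToChar(raw[1:2]) != "II" || u2(3) != 42)
    bad("header (expect little-endian II42)")
  ifd <- u4(5)
  pages <- list(); descriptions <- character()
  while (ifd != 0) {
    ntag <- u2(ifd + 1)
    tags <- list()
    for (t in seq_len(ntag)) {
      at <- ifd + 2 + (t - 1) * 12
      code <- u2(at + 1); typ <- u2(at + 3); count <- u4(at + 5)
      val <- if (typ == 3 && count == 1) u2(at + 9) else u4(at + 9)
      tags[[as.character(code)]] <- list(type = typ, count = count,
                                         value = val)
    }
    need <- function(code) {
      tg <- tags[[as.character(code)]]
      if (is.null(tg)) bad(sprintf("missing tag %d", code))
      tg
    }
    w <- need(256)$value; h <- need(257)$value
    bps <- need(258)$value
    if (!is.null(tags[["259"]]) && tags[["259"]]$value != 1)
      bad("compressed data not supported")
    fmt <- if (is.null(tags[["339"]])) 1 else tags[["339"]]$value
    so <- need(273)
    if (so$count != 1) bad("multi-strip pages not supported")
    nbytes <- need(279)$value
    if (nbytes != w * h * bps / 8) bad("StripByteCounts inconsistent")
    at <- so$value
    vals <- if (fmt == 3 && bps == 32)
      readBin(raw[(at + 1):(at + nbytes)], "double", n = w * h, size = 4,
              endian = "little")
    else if (fmt == 1 && bps %in% c(8, 16))
      readBin(raw[(at + 1):(at + nbytes)], "integer", n = w * h,
              size = bps / 8, signed = FALSE, endian = "little")
    else bad(sprintf("unsupported sample format %d/%d bits", fmt, bps))
    pages[[length(pages) + 1L]] <- matrix(vals, h, w, byrow = TRUE)
    desc <- ""
    dt <- tags[["270"]]
    if (!is.null(dt) && dt$count > 0) {
      dr <- if (dt$count <= 4) {
        at2 <- ifd + 2 + (which(names(tags) == "270") - 1) * 12 + 9
        raw[at2:(at2 + dt$count - 1)]
      } else raw[(dt$value + 1):(dt$value + dt$count)]
      dr <- dr[dr != as.raw(0)]
      desc <- rawToChar(dr)
    }
    descriptions <- c(descriptions, desc)
    ifd <- u4(ifd + 2 + ntag * 12 + 1)
  }
  list(pages = pages, descriptions = descriptions)
}
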