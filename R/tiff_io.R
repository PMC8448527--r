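# Minimal baseline-TIFF I/O for fluorescence stacks.
#
# No TIFF package is available in the deployment environment, so the subset
# of the format this package needs is implemented here: little-endian,
# uncompressed, single-strip, 16-bit unsigned grayscale, multi-page, with
# ImageJ-style calibration (frame interval in the ImageDescription of the
# first page, pixel size as X/YResolution in pixels per micrometre).

.TIFF_TYPE_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

.tiff_entry <- function(tag, type, count, value, offset = NULL) {
  # returns 12 raw bytes; `value` inline when it fits, else `offset` is used
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (!is.null(offset)) {
    writeBin(as.integer(offset), con, size = 4, endian = "little")
  } else if (type == 3L) {                       # SHORT, count 1
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {                                       # LONG, count 1
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  rawConnectionValue(con)
}

#' Write a movie stack as a multi-page 16-bit TIFF
#'
#' Writes an uncompressed little-endian grayscale TIFF with one page per
#' frame. ImageJ-compatible calibration is embedded: the frame interval
#' (`finterval`, seconds) and spatial unit in the ImageDescription, and the
#' pixel size as X/YResolution. Intensities are rounded to the nearest
#' integer and must fit 0..65535 after rounding; values pushed below zero
#' by noise are clamped with a warning.
#'
#' @param movie a [movie_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie$data)
  n <- d[1]; h <- d[2]; w <- d[3]
  px <- round(movie$data)
  if (any(px < 0)) {
    warning("negative intensities clamped to 0")
    px[px < 0] <- 0
  }
  if (any(px > 65535)) stop("intensities exceed 16-bit range", call. = FALSE)

  desc <- sprintf(
    "ImageJ=1.53t\nimages=%d\nframes=%d\nfinterval=%.9g\nunit=um\n",
    n, n, 1 / movie$frame_rate)
  desc_raw <- c(charToRaw(desc), as.raw(0))
  if (length(desc_raw) %% 2L) desc_raw <- c(desc_raw, as.raw(0))

  hdr_len <- 8L
  desc_off <- hdr_len
  res_off <- desc_off + length(desc_raw)
  data0 <- res_off + 8L
  page_bytes <- h * w * 2L
  ifd0 <- data0 + n * page_bytes

  # resolution rational: pixels per um = 1 / pixel_size
  res_num <- 1000000L
  res_den <- as.integer(round(movie$pixel_size * 1e6))

  ifd_bytes <- function(first) 2L + 12L * (if (first) 14L else 13L) + 4L
  ifd_offsets <- ifd0 + cumsum(c(0L, vapply(seq_len(max(n - 1L, 0L)),
    function(i) ifd_bytes(i == 1L), integer(1))))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_offsets[1]), con, size = 4, endian = "little")
  writeBin(desc_raw, con)
  writeBin(res_num, con, size = 4, endian = "little")
  writeBin(res_den, con, size = 4, endian = "little")
  for (t in seq_len(n)) {
    v <- as.integer(t(px[t, , ]))                # row-major scanlines
    v[v > 32767L] <- v[v > 32767L] - 65536L      # two's complement for writeBin
    writeBin(v, con, size = 2, endian = "little")
  }
  for (t in seq_len(n)) {
    first <- t == 1L
    entries <- list(
      .tiff_entry(256, 4, 1, w),
      .tiff_entry(257, 4, 1, h),
      .tiff_entry(258, 3, 1, 16),
      .tiff_entry(259, 3, 1, 1),
      .tiff_entry(262, 3, 1, 1))
    if (first)
      entries <- c(entries,
                   list(.tiff_entry(270, 2, length(desc_raw), offset = desc_off)))
    entries <- c(entries, list(
      .tiff_entry(273, 4, 1, data0 + (t - 1L) * page_bytes),
      .tiff_entry(277, 3, 1, 1),
      .tiff_entry(278, 4, 1, h),
      .tiff_entry(279, 4, 1, page_bytes),
      .tiff_entry(282, 5, 1, offset = res_off),
      .tiff_entry(283, 5, 1, offset = res_off),
      .tiff_entry(296, 3, 1, 1),
      .tiff_entry(339, 3, 1, 1)))
    writeBin(as.integer(length(entries)), con, size = 2, endian = "little")
    for (e in entries) writeBin(e, con)
    nxt <- if (t < n) ifd_offsets[t + 1L] else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

.read_u16 <- function(con, n = 1L) readBin(con, "integer", n = n, size = 2,
                                           endian = "little", signed = FALSE)
.read_u32 <- function(con, n = 1L) {
  v <- readBin(con, "integer", n = n, size = 4, endian = "little")
  ifelse(v < 0, v + 2^32, v)
}

#' Read a multi-page TIFF into a movie stack
#'
#' Supports the baseline grayscale subset written by [write_movie()]
#' (uncompressed, little-endian, 8- or 16-bit unsigned, strip layout).
#' The frame interval is taken from ImageJ `finterval` metadata and the
#' pixel size from X-resolution; if a calibration is absent from both the
#' file and the arguments, reading fails loudly rather than guessing.
#'
#' @param path TIFF file path.
#' @param frame_rate,pixel_size fallback calibration used only when the
#'   file carries none.
#' @return a [movie_stack()].
#' @export
read_movie <- function(path, frame_rate = NULL, pixel_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  byte_order <- readChar(con, 2, useBytes = TRUE)
  if (byte_order != "II")
    stop("unsupported TIFF byte order (only little-endian supported)", call. = FALSE)
  if (.read_u16(con) != 42L) stop("not a TIFF file", call. = FALSE)
  ifd_off <- .read_u32(con)

  pages <- list()
  desc <- NULL
  xres <- NULL
  while (ifd_off != 0) {
    seek(con, ifd_off)
    n_ent <- .read_u16(con)
    tags <- list()
    for (i in seq_len(n_ent)) {
      tag <- .read_u16(con); type <- .read_u16(con); count <- .read_u32(con)
      val_raw <- readBin(con, "raw", n = 4)
      tags[[as.character(tag)]] <- list(type = type, count = count, raw = val_raw)
    }
    next_off <- .read_u32(con)

    getv <- function(tag) {
      e <- tags[[as.character(tag)]]
      if (is.null(e)) return(NULL)
      sz <- .TIFF_TYPE_SIZES[as.character(e$type)]
      total <- sz * e$count
      read_from <- function(cn) {
        if (e$type == 3L) .read_u16(cn, e$count)
        else if (e$type == 4L) .read_u32(cn, e$count)
        else if (e$type == 2L) readBin(cn, "raw", n = e$count)
        else if (e$type == 5L) .read_u32(cn, 2L * e$count)
        else stop("unsupported TIFF field type ", e$type, call. = FALSE)
      }
      if (total <= 4) {
        cn <- rawConnection(e$raw); on.exit(close(cn), add = TRUE)
        read_from(cn)
      } else {
        off_cn <- rawConnection(e$raw); off <- .read_u32(off_cn); close(off_cn)
        pos <- seek(con)
        seek(con, off)
        out <- read_from(con)
        seek(con, pos)
        out
      }
    }

    w <- getv(256); h <- getv(257)
    bits <- getv(258); comp <- getv(259)
    if (is.null(w) || is.null(h)) stop("malformed TIFF page", call. = FALSE)
    if (!is.null(comp) && comp[1] != 1L)
      stop("compressed TIFF not supported", call. = FALSE)
    bits <- if (is.null(bits)) 1L else bits[1]
    if (!bits %in% c(8L, 16L))
      stop("only 8/16-bit grayscale supported", call. = FALSE)
    if (is.null(desc)) {
      d <- getv(270)
      if (!is.null(d)) desc <- rawToChar(d[d != as.raw(0)])
    }
    if (is.null(xres)) {
      r <- getv(282)
      if (!is.null(r) && r[2] != 0) xres <- r[1] / r[2]
    }
    offs <- getv(273); cnts <- getv(279)
    if (is.null(offs)) stop("TIFF page without strip offsets", call. = FALSE)
    if (is.null(cnts)) cnts <- rep(w * h * bits / 8 / length(offs), length(offs))
    px <- integer(0)
    for (s in seq_along(offs)) {
      seek(con, offs[s])
      n_val <- cnts[s] / (bits / 8)
      px <- c(px, if (bits == 16L) .read_u16(con, n_val)
              else as.integer(readBin(con, "raw", n = n_val)))
    }
    pages[[length(pages) + 1L]] <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
    ifd_off <- next_off
  }
  if (!length(pages)) stop("TIFF contains no pages", call. = FALSE)

  fr <- frame_rate
  if (!is.null(desc)) {
    m <- regmatches(desc, regexec("finterval=([0-9.eE+-]+)", desc))[[1]]
    if (length(m) == 2) {
      fi <- as.numeric(m[2])
      if (is.finite(fi) && fi > 0) fr <- 1 / fi
    }
  }
  if (is.null(fr))
    stop("no frame-interval calibration in file and none supplied", call. = FALSE)
  ps <- pixel_size
  if (!is.null(xres) && xres > 0) ps <- 1 / xres
  if (is.null(ps))
    stop("no pixel-size calibration in file and none supplied", call. = FALSE)

  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  data <- array(0, dim = c(length(pages), h, w))
  for (t in seq_along(pages)) data[t, , ] <- pages[[t]]
  movie_stack(data, frame_rate = fr, pixel_size = ps)
}
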