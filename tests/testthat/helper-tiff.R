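# Hand-rolled single-page bare TIFF (no calibration metadata), written
# independently of the package's writer; exercises read_movie's calibration
# failure path and doubles as a structural oracle for the reader.
make_bare_tiff <- function(path, mat) {
  h <- nrow(mat); w <- ncol(mat)
  con <- file(path, "wb")
  on.exit(close(con))
  data_off <- 8L
  nbytes <- h * w * 2L
  ifd_off <- data_off + nbytes
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off, con, size = 4, endian = "little")
  v <- as.integer(t(mat))
  v[v > 32767L] <- v[v > 32767L] - 65536L
  writeBin(v, con, size = 2, endian = "little")
  ent <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  writeBin(8L, con, size = 2, endian = "little")   # 8 entries
  ent(256, 4, 1, w); ent(257, 4, 1, h); ent(258, 3, 1, 16)
  ent(259, 3, 1, 1); ent(262, 3, 1, 1); ent(273, 4, 1, data_off)
  ent(278, 4, 1, h); ent(279, 4, 1, nbytes)
  writeBin(0L, con, size = 4, endian = "little")
  invisible(path)
}
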