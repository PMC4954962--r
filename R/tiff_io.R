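#' Read a grayscale TIFF image
#'
#' Minimal baseline-TIFF reader covering the files this package writes and
#' typical single-channel microscope exports: uncompressed, 8- or 16-bit
#' unsigned grayscale, little- or big-endian, single or multiple strips.
#' Only the first image (IFD) of a file is read.
#'
#' @param path Path to a `.tif`/`.tiff` file.
#' @return Integer matrix of pixel intensities (rows x cols, grayscale units).
#' @seealso [write_tiff_gray()]
#' @export
read_tiff_gray <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  endian <- if (identical(magic[1:2], as.raw(c(0x49, 0x49)))) "little"
            else if (identical(magic[1:2], as.raw(c(0x4d, 0x4d)))) "big"
            else stop("not a TIFF file: ", path)
  u16 <- function() readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = endian)
  u32 <- function() readBin(con, "integer", 1L, size = 4L, endian = endian)
  ifd_off <- u32()
  seek(con, ifd_off)
  n_tags <- u16()
  tags <- list()
  for (i in seq_len(n_tags)) {
    tag <- u16(); typ <- u16(); cnt <- u32()
    # value field is 4 bytes: inline if it fits, else an offset
    tsize <- c(1L, 1L, 2L, 4L, 8L)[typ]
    if (is.na(tsize)) { readBin(con, "raw", 4L); next }
    if (tsize * cnt <= 4L) {
      here <- seek(con)
      vals <- if (typ == 3L) {
        readBin(con, "integer", cnt, size = 2L, signed = FALSE, endian = endian)
      } else if (typ == 4L) {
        readBin(con, "integer", cnt, size = 4L, endian = endian)
      } else {
        readBin(con, "integer", cnt, size = 1L, signed = FALSE, endian = endian)
      }
      seek(con, here + 4L)
    } else {
      off <- u32(); here <- seek(con)
      seek(con, off)
      vals <- if (typ == 3L) {
        readBin(con, "integer", cnt, size = 2L, signed = FALSE, endian = endian)
      } else if (typ == 4L) {
        readBin(con, "integer", cnt, size = 4L, endian = endian)
      } else if (typ == 5L) {
        readBin(con, "integer", 2L * cnt, size = 4L, endian = endian)
      } else {
        readBin(con, "integer", cnt, size = 1L, signed = FALSE, endian = endian)
      }
      seek(con, here)
    }
    tags[[as.character(tag)]] <- vals
  }
  need <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF tag ", id, " missing in ", path)
      default
    } else v
  }
  width  <- need(256L)
  height <- need(257L)
  bits   <- need(258L, 1L)[1]
  comp   <- need(259L, 1L)
  if (comp != 1L) stop("only uncompressed TIFF supported (compression=", comp, ")")
  spp <- need(277L, 1L)
  if (spp != 1L) stop("only single-channel grayscale TIFF supported")
  if (!bits %in% c(8L, 16L)) stop("only 8/16-bit TIFF supported (bits=", bits, ")")
  offsets <- need(273L)
  counts  <- need(279L, as.integer(width * height * bits / 8))
  rps     <- need(278L, height)
  px <- integer(0)
  for (s in seq_along(offsets)) {
    seek(con, offsets[s])
    n_px <- counts[s] / (bits / 8L)
    px <- c(px, readBin(con, "integer", n_px, size = bits / 8L,
                        signed = FALSE, endian = endian))
  }
  if (length(px) != width * height) stop("truncated TIFF pixel data in ", path)
  # TIFF stores rows (scanlines) consecutively
  matrix(px, nrow = height, ncol = width, byrow = TRUE)
}

#' Write a 16-bit grayscale TIFF image
#'
#' Writes an uncompressed single-strip little-endian baseline TIFF with
#' 16-bit unsigned pixels, the acquisition format of the screening camera.
#' Values are clipped to `[0, 65535]` and rounded.
#'
#' @param pixels Numeric or integer matrix of intensities.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_gray <- function(pixels, path) {
  stopifnot(is.matrix(pixels))
  px <- as.integer(round(pmin(pmax(pixels, 0), 65535)))
  nr <- nrow(pixels); nc <- ncol(pixels)
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  data_off <- 8L
  n_bytes <- nr * nc * 2L
  ifd_off <- data_off + n_bytes
  writeBin(as.raw(c(0x49, 0x49)), con); w16(42L); w32(ifd_off)
  # pixel data, row-major scanlines; writeBin keeps the low 16 bits
  m <- matrix(px, nr, nc)
  writeBin(as.vector(t(m)), con, size = 2L, endian = "little")
  tag <- function(id, typ, cnt, val) { w16(id); w16(typ); w32(cnt); w32(val) }
  entries <- list(
    c(256L, 4L, 1L, nc),        # ImageWidth
    c(257L, 4L, 1L, nr),        # ImageLength
    c(258L, 3L, 1L, 16L),       # BitsPerSample
    c(259L, 3L, 1L, 1L),        # Compression: none
    c(262L, 3L, 1L, 1L),        # Photometric: BlackIsZero
    c(273L, 4L, 1L, data_off),  # StripOffsets
    c(277L, 3L, 1L, 1L),        # SamplesPerPixel
    c(278L, 4L, 1L, nr),        # RowsPerStrip
    c(279L, 4L, 1L, n_bytes),   # StripByteCounts
    c(339L, 3L, 1L, 1L)         # SampleFormat: unsigned int
  )
  w16(length(entries))
  for (e in entries) tag(e[1], e[2], e[3], e[4])
  w32(0L)  # no next IFD
  invisible(path)
}
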