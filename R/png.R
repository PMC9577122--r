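# Minimal PNG codec for 8-bit RGB rasters.
#
# The pre-installed R stack guarantees no PNG package, so the package ships
# its own reader/writer: zlib streams via memCompress()/memDecompress()
# (base R emits RFC-1950 zlib format, which is what IDAT requires), CRC32
# and scanline (un)filtering in compiled code.  Writing always uses filter
# type 0; reading understands all five standard filters.  Only 8-bit,
# non-interlaced truecolour (colour type 2) images are supported, which is
# exactly what the synthetic-slide generator emits.

png_sig <- function() as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A))

int_to_be4 <- function(x) {
  x <- as.double(x)  # may exceed .Machine$integer.max (unsigned CRC32)
  as.raw(c(x %/% 16777216 %% 256, x %/% 65536 %% 256, x %/% 256 %% 256, x %% 256))
}
be4_to_int <- function(r) readBin(r, "integer", n = 1L, size = 4L, endian = "big", signed = TRUE)

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- .crc32(body, 0)
  c(int_to_be4(length(data)), body, int_to_be4(crc))
}

#' Write an 8-bit RGB image array as a PNG file
#'
#' @param img Integer (or numeric, rounded and clamped) H x W x 3 array with
#'   values in 0..255.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_png_rgb <- function(img, path) {
  assert_rgb(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  v <- as.vector(aperm(img, c(3, 2, 1)))  # interleaved RGB, row-major
  v <- as.integer(pmin(pmax(round(v), 0), 255))
  pixels <- as.raw(v)
  ihdr <- c(int_to_be4(w), int_to_be4(h),
            as.raw(c(8L, 2L, 0L, 0L, 0L)))  # depth 8, truecolour, no interlace
  idat <- memCompress(.png_filter0(pixels, w, h, 3L), type = "gzip")
  out <- c(png_sig(),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Read an 8-bit RGB PNG file into an image array
#'
#' @param path PNG file path (8-bit truecolour, non-interlaced).
#' @return Integer H x W x 3 array with values in 0..255.
#' @export
read_png_rgb <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  assert_that(length(raw_all) > 8 && identical(raw_all[1:8], png_sig()),
              sprintf("'%s' is not a PNG file", path))
  pos <- 9L
  width <- height <- NULL
  idat <- list()
  while (pos + 8 <= length(raw_all)) {
    len <- be4_to_int(raw_all[pos:(pos + 3L)])
    type <- rawToChar(raw_all[(pos + 4L):(pos + 7L)])
    data <- if (len > 0) raw_all[(pos + 8L):(pos + 7L + len)] else raw(0)
    if (type == "IHDR") {
      width <- be4_to_int(data[1:4]); height <- be4_to_int(data[5:8])
      depth <- as.integer(data[9]); ctype <- as.integer(data[10])
      interlace <- as.integer(data[13])
      assert_that(depth == 8L && ctype == 2L && interlace == 0L,
                  "only 8-bit non-interlaced RGB PNGs are supported")
    } else if (type == "IDAT") {
      idat[[length(idat) + 1L]] <- data
    } else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  assert_that(!is.null(width) && length(idat) > 0, "malformed PNG: missing IHDR/IDAT")
  stream <- memDecompress(do.call(c, idat), type = "gzip")
  pixels <- .png_unfilter(stream, width, height, 3L)
  v <- as.integer(pixels)
  img <- aperm(array(v, dim = c(3L, width, height)), c(3, 2, 1))
  storage.mode(img) <- "integer"
  img
}
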