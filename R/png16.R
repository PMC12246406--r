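# Minimal 16-bit grayscale PNG writer.
#
# The exchange format for phantom mammograms is 16-bit grayscale PNG; the
# installed image stacks read 16-bit PNGs but only write 8 bits per
# sample, so the writer is implemented here: IHDR (bit depth 16, color
# type 0), one zlib-wrapped IDAT with filter-0 scanlines, IEND. The
# DEFLATE stream is produced by memCompress and rewrapped from the gzip
# container into the zlib container PNG requires.

.crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1))  # 0xEDB88320
      else bitwShiftR(bitwAnd(c, -2L), 1)
    }
    tab[n + 1] <- c
  }
  tab
})

crc32_raw <- function(bytes) {
  crc <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    idx <- bitwAnd(bitwXor(crc, b[i]), 255L)
    crc <- bitwXor(bitwShiftR(bitwAnd(crc, -256L), 8), .crc32_table[idx + 1])
  }
  bitwXor(crc, -1L)
}

int_be <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "big")

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- crc32_raw(body)
  c(int_be(length(data)), body, writeBin(crc, raw(), size = 4,
                                         endian = "big"))
}

#' Write a matrix as a 16-bit grayscale PNG
#'
#' @param img Numeric matrix in `[0, 1]` (rows = image rows).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_png16 <- function(img, path) {
  h <- nrow(img); w <- ncol(img)
  u <- matrix(as.integer(round(clamp(img, 0, 1) * 65535)), h, w)
  hi <- u %/% 256L; lo <- u %% 256L
  scan <- array(0L, c(2L * w + 1L, h))
  scan[seq(2, 2 * w, by = 2), ] <- t(hi)
  scan[seq(3, 2 * w + 1, by = 2), ] <- t(lo)
  data <- as.raw(as.vector(scan))
  # memCompress("gzip") emits a zlib (RFC 1950) stream with adler32
  # trailer, which is exactly the IDAT payload PNG requires
  idat <- memCompress(data, "gzip")
  stopifnot(idat[1] == as.raw(0x78))
  ihdr <- c(int_be(w), int_be(h),
            as.raw(c(16, 0, 0, 0, 0)))  # depth 16, gray, std methods
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
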