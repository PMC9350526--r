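# Minimal 16-bit grayscale PNG encoder, used only to build test fixtures at
# run time (the png package reads 16-bit files but writes 8-bit ones).

crc32_table <- local({
  poly <- -306674912L  # 0xEDB88320 as signed 32-bit
  vapply(0:255, function(n) {
    c <- as.integer(n)
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(poly, bitwShiftR(c, 1L))
      } else {
        bitwShiftR(c, 1L)
      }
    }
    c
  }, integer(1))
})

crc32 <- function(bytes) {
  c <- -1L
  for (b in as.integer(bytes)) {
    c <- bitwXor(crc32_table[bitwAnd(bitwXor(c, b), 255L) + 1L],
                 bitwShiftR(c, 8L))
  }
  bitwXor(c, -1L)
}

u32_be <- function(x) {
  x <- as.numeric(x)
  if (x < 0) x <- x + 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 2^8) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_be(length(data)), body, u32_be(crc32(body)))
}

# Despite the argument name, memCompress(type = "gzip") emits a zlib
# (RFC 1950) stream, which is exactly what a PNG IDAT chunk wants.
zlib_compress <- function(bytes) memCompress(bytes, type = "gzip")

# values: integer matrix in 0..65535, written row by row (PNG scanlines).
write_png16 <- function(values, path) {
  H <- nrow(values); W <- ncol(values)
  scan <- raw(0)
  for (i in seq_len(H)) {
    v <- as.numeric(values[i, ])
    scan <- c(scan, as.raw(0L), as.raw(rbind(v %/% 256, v %% 256)))
  }
  ihdr <- c(u32_be(W), u32_be(H), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zlib_compress(scan)),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
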