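# Stimulus image I/O: 16-bit grayscale PNG plus a JSON sidecar carrying the
# generating spec and the luminance scaling.
#
# Reading goes through png::readPNG (which handles 16-bit natively); writing
# uses a small built-in encoder because the installed raster packages only
# emit 8-bit PNGs, which would quantise luminance to ~0.4% steps.

crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1))  # 0xEDB88320
      } else {
        bitwShiftR(bitwAnd(c, -2L), 1)
      }
    }
    tab[i + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(c, b), 255L)
    c <- bitwXor(crc32_table[idx + 1], bitwShiftR(bitwAnd(c, -256L), 8))
  }
  bitwXor(c, -1L)
}

adler32 <- function(bytes) {
  MOD <- 65521
  a <- 1; b <- 0
  # process in chunks to stay vectorised; 5552 is the largest block for
  # which intermediate sums fit in double precision exactly
  v <- as.integer(bytes)
  i <- 1L
  while (i <= length(v)) {
    j <- min(i + 5551L, length(v))
    chunk <- v[i:j]
    b <- (b + length(chunk) * a + sum(cumsum(chunk))) %% MOD
    a <- (a + sum(chunk)) %% MOD
    i <- j + 1L
  }
  b * 65536 + a
}

u32_bytes <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- crc32(body) %% 2^32
  c(u32_bytes(length(data)), body, u32_bytes(crc))
}

# zlib stream for the PNG IDAT chunk.  R's memCompress(type = "gzip")
# emits a zlib-wrapped stream (0x78 header) on most builds, which is what
# PNG wants; if a build emits true gzip framing instead, re-wrap the
# deflate payload with a zlib header and Adler-32 checksum.
zlib_compress <- function(bytes) {
  gz <- memCompress(bytes, type = "gzip")
  if (as.integer(gz[1]) == 0x78) return(gz)
  deflate <- gz[11:(length(gz) - 8)]  # strip gzip header and trailer
  c(as.raw(c(0x78, 0x9c)), deflate, u32_bytes(adler32(bytes)))
}

write_png16 <- function(u16, path) {
  h <- nrow(u16); w <- ncol(u16)
  ihdr <- c(u32_bytes(w), u32_bytes(h),
            as.raw(c(16, 0, 0, 0, 0)))  # bit depth 16, grayscale
  hi <- as.raw(u16 %/% 256L)
  lo <- as.raw(u16 %% 256L)
  rows <- vector("list", h)
  for (r in seq_len(h)) {
    px <- rbind(hi[seq(r, length(hi), by = h)], lo[seq(r, length(lo), by = h)])
    rows[[r]] <- c(as.raw(0), as.vector(px))  # filter type 0 per scanline
  }
  raw_data <- unlist(rows)
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zlib_compress(raw_data)),
           png_chunk("IEND", raw()))
  writeBin(out, path)
  invisible(path)
}

#' Write a stimulus as a 16-bit grayscale PNG with a JSON sidecar
#'
#' Luminance is mapped linearly from `[0, lum_max]` to the 16-bit range;
#' the sidecar (`<path>.json`) records the scaling, the degrees-per-pixel,
#' and (when supplied) the generating [stimulus_spec()], so the image can
#' be read back in physical units with [read_stimulus_png()].
#'
#' @param img A `cl_luminance_image`.
#' @param path Output PNG path.
#' @param spec Optional generating [stimulus_spec()], stored in the sidecar.
#' @param lum_max Luminance mapped to white; defaults to twice the
#'   background luminance (the maximum attainable at 100% contrast).
#' @return `path`, invisibly.
#' @export
write_stimulus_png <- function(img, path, spec = NULL, lum_max = NULL) {
  stopifnot(inherits(img, "cl_luminance_image"))
  if (is.null(lum_max)) lum_max <- 2 * attr(img, "background")
  if (max(img) > lum_max) abort("`lum_max` smaller than the image maximum.")
  u16 <- matrix(as.integer(round(unclass(img) / lum_max * 65535)),
                nrow(img), ncol(img))
  write_png16(u16, path)
  sidecar <- list(
    degrees_per_pixel = attr(img, "degrees_per_pixel"),
    background = attr(img, "background"),
    lum_max = lum_max,
    spec = if (!is.null(spec)) unclass(spec)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a stimulus written by [write_stimulus_png()]
#'
#' @param path PNG path (the sidecar `<path>.json` must sit next to it).
#' @return A `cl_luminance_image` in cd/m2.
#' @export
read_stimulus_png <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- png::readPNG(path) * side$lum_max
  structure(v,
            degrees_per_pixel = side$degrees_per_pixel,
            background = side$background,
            class = c("cl_luminance_image", "matrix", "array"))
}
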