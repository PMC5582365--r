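# Minimal 8-bit PNG codec in base R.
#
# No PNG-capable package is assumed: IDAT streams are RFC-1950 zlib, which
# base memCompress()/memDecompress(type = "gzip") produce and accept, and
# chunk CRC32s are computed with a table-driven loop. Supported pixel
# formats are 8-bit grayscale (color type 0) and 8-bit RGB (color type 2),
# non-interlaced; images with alpha (color types 4/6) are rejected with a
# clear error rather than silently flattened.

.aminoblot_cache <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (!is.null(.aminoblot_cache$crc_tab)) return(.aminoblot_cache$crc_tab)
  poly <- -306674912L # 0xEDB88320 as signed 32-bit
  tab <- integer(256L)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(poly, bitwShiftR(c, 1L)) else bitwShiftR(c, 1L)
    }
    tab[n + 1L] <- c
  }
  .aminoblot_cache$crc_tab <- tab
  tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  ints <- as.integer(bytes)
  for (b in ints) {
    crc <- bitwXor(tab[bitwAnd(bitwXor(crc, b), 255L) + 1L], bitwShiftR(crc, 8L))
  }
  bitwXor(crc, -1L)
}

u32_to_raw_be <- function(x) {
  # x: signed 32-bit integer carrying unsigned payload, or double < 2^31
  x <- as.integer(x)
  as.raw(c(bitwAnd(bitwShiftR(x, 24L), 255L), bitwAnd(bitwShiftR(x, 16L), 255L),
           bitwAnd(bitwShiftR(x, 8L), 255L), bitwAnd(x, 255L)))
}

raw_be_to_num <- function(bytes) {
  sum(as.numeric(bytes) * 256^((length(bytes) - 1):0))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_to_raw_be(length(data)), body, u32_to_raw_be(crc32(body)))
}

image_to_scanlines <- function(image) {
  if (inherits(image, "gray_image")) {
    q <- round_half_away(unclass(image))
    h <- nrow(q); w <- ncol(q)
    bytes <- as.raw(as.vector(t(q)))
    bpr <- w
    color_type <- 0L
  } else if (inherits(image, "rgb_image")) {
    a <- unclass(image)
    h <- dim(a)[1]; w <- dim(a)[2]
    bytes <- as.raw(as.vector(aperm(a, c(3L, 2L, 1L)))) # channel, col, row
    bpr <- 3L * w
    color_type <- 2L
  } else {
    stopf("expected an rgb_image or gray_image", class = "aminoblot_shape_error")
  }
  m <- matrix(as.raw(0L), nrow = bpr + 1L, ncol = h) # row 1 = filter byte 0
  m[-1L, ] <- matrix(bytes, nrow = bpr, ncol = h)
  list(stream = as.vector(m), width = w, height = h, color_type = color_type)
}

#' Write an image as 8-bit PNG
#'
#' Grayscale images are quantized with the export rounding rule (round half
#' away from zero) and written as single-channel PNG; RGB images are written
#' as 8-bit truecolor.
#'
#' @param image an [rgb_image()] or [gray_image()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(image, path) {
  sl <- image_to_scanlines(image)
  ihdr <- c(u32_to_raw_be(sl$width), u32_to_raw_be(sl$height),
            as.raw(c(8L, sl$color_type, 0L, 0L, 0L)))
  idat <- memCompress(sl$stream, type = "gzip") # emits a zlib stream
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

unfilter_scanlines <- function(data, filters, bpp) {
  # data: bpr x h integer matrix of filtered bytes; returns defiltered bytes
  bpr <- nrow(data); h <- ncol(data)
  prev <- integer(bpr)
  for (r in seq_len(h)) {
    cur <- data[, r]
    f <- filters[r]
    if (f == 1L) {        # Sub
      for (off in seq_len(bpp)) {
        idx <- seq.int(off, bpr, by = bpp)
        cur[idx] <- cumsum(cur[idx]) %% 256L
      }
    } else if (f == 2L) { # Up
      cur <- (cur + prev) %% 256L
    } else if (f == 3L) { # Average
      for (i in seq_len(bpr)) {
        left <- if (i > bpp) cur[i - bpp] else 0L
        cur[i] <- (cur[i] + (left + prev[i]) %/% 2L) %% 256L
      }
    } else if (f == 4L) { # Paeth
      for (i in seq_len(bpr)) {
        a <- if (i > bpp) cur[i - bpp] else 0L
        b <- prev[i]
        cc <- if (i > bpp) prev[i - bpp] else 0L
        p <- a + b - cc
        pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - cc)
        pred <- if (pa <= pb && pa <= pc) a else if (pb <= pc) b else cc
        cur[i] <- (cur[i] + pred) %% 256L
      }
    } else if (f != 0L) {
      stopf("unsupported PNG filter type %d", f, class = "aminoblot_format_error")
    }
    data[, r] <- cur
    prev <- cur
  }
  data
}

scanlines_to_image <- function(stream, width, height, color_type) {
  bpp <- if (color_type == 2L) 3L else 1L
  bpr <- width * bpp
  if (length(stream) != height * (bpr + 1L)) {
    stopf("PNG data length inconsistent with header", class = "aminoblot_format_error")
  }
  m <- matrix(as.integer(stream), nrow = bpr + 1L, ncol = height)
  pix <- unfilter_scanlines(m[-1L, , drop = FALSE], m[1L, ], bpp)
  if (color_type == 2L) {
    rgb_image(aperm(array(as.numeric(pix), dim = c(3L, width, height)), c(3L, 2L, 1L)))
  } else {
    gray_image(t(matrix(as.numeric(pix), nrow = width, ncol = height)))
  }
}

#' Read an 8-bit PNG image
#'
#' Supports non-interlaced 8-bit grayscale and RGB. Images carrying an alpha
#' channel or a palette are rejected with an informative error: calibrated
#' intensity work needs unambiguous channel semantics.
#'
#' @param path file path.
#' @return an [rgb_image()] (truecolor files) or [gray_image()] (grayscale
#'   files).
#' @export
read_png <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  sig <- as.raw(c(137, 80, 78, 71, 13, 10, 26, 10))
  if (length(bytes) < 8L || !identical(bytes[1:8], sig)) {
    stopf("%s is not a PNG file", path, class = "aminoblot_format_error")
  }
  pos <- 9L
  width <- height <- color_type <- NULL
  idat <- list()
  while (pos + 7L <= length(bytes)) {
    len <- raw_be_to_num(bytes[pos:(pos + 3L)])
    type <- rawToChar(bytes[(pos + 4L):(pos + 7L)])
    dstart <- pos + 8L
    data <- if (len > 0) bytes[dstart:(dstart + len - 1L)] else raw(0)
    if (type == "IHDR") {
      width <- raw_be_to_num(data[1:4]); height <- raw_be_to_num(data[5:8])
      bitdepth <- as.integer(data[9]); color_type <- as.integer(data[10])
      interlace <- as.integer(data[13])
      if (bitdepth != 8L) stopf("only 8-bit PNG is supported (got bit depth %d)",
                                bitdepth, class = "aminoblot_format_error")
      if (color_type %in% c(4L, 6L)) {
        stopf("PNG alpha channels are not supported; flatten the image first",
              class = "aminoblot_format_error")
      }
      if (!color_type %in% c(0L, 2L)) {
        stopf("unsupported PNG color type %d", color_type, class = "aminoblot_format_error")
      }
      if (interlace != 0L) stopf("interlaced PNG is not supported",
                                 class = "aminoblot_format_error")
    } else if (type == "IDAT") {
      idat[[length(idat) + 1L]] <- data
    } else if (type == "IEND") {
      break
    }
    pos <- dstart + len + 4L # skip CRC
  }
  if (is.null(width) || length(idat) == 0L) {
    stopf("PNG file %s is missing IHDR or IDAT", path, class = "aminoblot_format_error")
  }
  stream <- memDecompress(do.call(c, idat), type = "gzip")
  scanlines_to_image(stream, as.integer(width), as.integer(height), color_type)
}
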