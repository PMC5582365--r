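# Minimal baseline TIFF codec: 8-bit grayscale or RGB, uncompressed,
# chunky planar layout, single IFD. Both byte orders are read; files are
# written little-endian. ExtraSamples (alpha) is rejected.

u16_le <- function(x) as.raw(c(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L)))
u32_le <- function(x) {
  x <- as.integer(x)
  as.raw(c(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L),
           bitwAnd(bitwShiftR(x, 16L), 255L), bitwAnd(bitwShiftR(x, 24L), 255L)))
}

tiff_entry <- function(tag, type, count, value_raw4) {
  c(u16_le(tag), u16_le(type), u32_le(count), value_raw4)
}

#' Write an image as uncompressed 8-bit TIFF
#'
#' @inheritParams write_png
#' @return `path`, invisibly.
#' @export
write_tiff <- function(image, path) {
  sl <- image_to_scanlines(image) # reuse: filter bytes then stripped
  spp <- if (sl$color_type == 2L) 3L else 1L
  w <- sl$width; h <- sl$height
  pix <- matrix(sl$stream, nrow = spp * w + 1L)[-1L, , drop = FALSE]
  pix <- as.vector(pix)
  data_offset <- 8L
  nbytes <- length(pix)
  ifd_offset <- data_offset + nbytes
  photometric <- if (spp == 3L) 2L else 1L
  n_entries <- 9L
  bits_offset <- ifd_offset + 2L + 12L * n_entries + 4L
  bits_value <- if (spp == 3L) u32_le(bits_offset) else c(u16_le(8L), u16_le(0L))
  entries <- c(
    tiff_entry(256L, 4L, 1L, u32_le(w)),            # ImageWidth
    tiff_entry(257L, 4L, 1L, u32_le(h)),            # ImageLength
    tiff_entry(258L, 3L, spp, bits_value),          # BitsPerSample
    tiff_entry(259L, 3L, 1L, c(u16_le(1L), u16_le(0L))),   # Compression: none
    tiff_entry(262L, 3L, 1L, c(u16_le(photometric), u16_le(0L))),
    tiff_entry(273L, 4L, 1L, u32_le(data_offset)),  # StripOffsets
    tiff_entry(277L, 3L, 1L, c(u16_le(spp), u16_le(0L))),  # SamplesPerPixel
    tiff_entry(278L, 4L, 1L, u32_le(h)),            # RowsPerStrip
    tiff_entry(279L, 4L, 1L, u32_le(nbytes))        # StripByteCounts
  )
  out <- c(charToRaw("II"), u16_le(42L), u32_le(data_offset + nbytes),
           pix,
           u16_le(n_entries), entries, u32_le(0L))
  if (spp == 3L) out <- c(out, u16_le(8L), u16_le(8L), u16_le(8L))
  writeBin(out, path)
  invisible(path)
}

read_uint <- function(bytes, le) {
  p <- as.numeric(bytes)
  if (le) sum(p * 256^(seq_along(p) - 1)) else sum(p * 256^(rev(seq_along(p)) - 1))
}

#' Read an uncompressed 8-bit TIFF image
#'
#' Baseline grayscale or RGB TIFF only; alpha (ExtraSamples), compressed or
#' planar-separated files are rejected.
#'
#' @param path file path.
#' @return an [rgb_image()] or [gray_image()].
#' @export
read_tiff <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  order_tag <- rawToChar(bytes[1:2])
  le <- order_tag == "II"
  if (!le && order_tag != "MM") {
    stopf("%s is not a TIFF file", path, class = "aminoblot_format_error")
  }
  if (read_uint(bytes[3:4], le) != 42) {
    stopf("%s is not a TIFF file", path, class = "aminoblot_format_error")
  }
  ifd <- read_uint(bytes[5:8], le)
  n <- read_uint(bytes[ifd + 1:2], le)
  tags <- list()
  for (i in seq_len(n)) {
    e <- ifd + 2 + (i - 1) * 12
    tag <- read_uint(bytes[e + 1:2], le)
    type <- read_uint(bytes[e + 3:4], le)
    count <- read_uint(bytes[e + 5:8], le)
    size <- c(1, 1, 2, 4, 8)[type]
    total <- size * count
    val_bytes <- if (total <= 4) bytes[e + 9:12] else {
      off <- read_uint(bytes[e + 9:12], le)
      bytes[off + seq_len(total)]
    }
    vals <- vapply(seq_len(count), function(k) {
      read_uint(val_bytes[(k - 1) * size + seq_len(size)], le)
    }, numeric(1))
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stopf("TIFF missing required tag %d", tag,
                                  class = "aminoblot_format_error")
      default
    } else v
  }
  if (!is.null(tags[["338"]])) {
    stopf("TIFF alpha channels (ExtraSamples) are not supported",
          class = "aminoblot_format_error")
  }
  if (need(259, 1) != 1) stopf("compressed TIFF is not supported",
                               class = "aminoblot_format_error")
  if (need(284, 1) != 1) stopf("planar-separated TIFF is not supported",
                               class = "aminoblot_format_error")
  spp <- as.integer(need(277, 1))
  bits <- need(258, 8)
  if (any(bits != 8)) stopf("only 8-bit TIFF is supported",
                            class = "aminoblot_format_error")
  if (!spp %in% c(1L, 3L)) stopf("unsupported TIFF sample count %d", spp,
                                 class = "aminoblot_format_error")
  w <- as.integer(need(256)); h <- as.integer(need(257))
  offsets <- need(273); counts <- need(279)
  pix <- do.call(c, lapply(seq_along(offsets), function(k) {
    bytes[offsets[k] + seq_len(counts[k])]
  }))
  if (length(pix) != w * h * spp) {
    stopf("TIFF strip data inconsistent with dimensions",
          class = "aminoblot_format_error")
  }
  vals <- as.numeric(pix)
  if (spp == 3L) {
    rgb_image(aperm(array(vals, dim = c(3L, w, h)), c(3L, 2L, 1L)))
  } else {
    gray_image(t(matrix(vals, nrow = w, ncol = h)))
  }
}

#' Read or write an image, dispatching on file extension
#'
#' `.png` uses the PNG codec, `.tif`/`.tiff` the TIFF codec.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param image for `write_image`, an [rgb_image()] or [gray_image()].
#' @return `read_image` returns an image object; `write_image` returns
#'   `path` invisibly.
#' @export
read_image <- function(path) {
  switch(tolower(tools::file_ext(path)),
         png = read_png(path),
         tif = , tiff = read_tiff(path),
         stopf("unsupported image extension in %s", path,
               class = "aminoblot_format_error"))
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  switch(tolower(tools::file_ext(path)),
         png = write_png(image, path),
         tif = , tiff = write_tiff(image, path),
         stopf("unsupported image extension in %s", path,
               class = "aminoblot_format_error"))
}
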