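#' In-memory 8-bit RGB image
#'
#' An `rgb_image` is a `height x width x 3` numeric array with integer
#' channel values in \[0, 255\], 0-based pixel coordinates being the
#' convention at the interfaces (origin top-left, row-major). Internally the
#' usual R 1-based `img[row, col, channel]` addressing applies.
#'
#' @param data numeric array `h x w x 3` with values in \[0, 255\]; values
#'   must be whole numbers (8-bit samples).
#' @return an object of class `rgb_image`.
#' @export
rgb_image <- function(data) {
  if (!is.array(data) || length(dim(data)) != 3L || dim(data)[3] != 3L) {
    stopf("rgb_image data must be an h x w x 3 array", class = "aminoblot_shape_error")
  }
  if (anyNA(data) || min(data) < 0 || max(data) > 255) {
    stopf("rgb_image channel values must be in [0, 255]", class = "aminoblot_domain_error")
  }
  if (any(data != round(data))) {
    stopf("rgb_image channel values must be whole numbers", class = "aminoblot_domain_error")
  }
  structure(data, class = "rgb_image")
}

#' In-memory grayscale intensity image
#'
#' A `gray_image` is a `height x width` numeric matrix with real-valued
#' intensities in \[0, 255\]. Intensities stay real throughout the pipeline;
#' quantization to 8 bits happens only at image export
#' (round-half-away-from-zero).
#'
#' @param data numeric matrix with values in \[0.0, 255.0\].
#' @return an object of class `gray_image`.
#' @export
gray_image <- function(data) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stopf("gray_image data must be a numeric matrix", class = "aminoblot_shape_error")
  }
  if (anyNA(data) || min(data) < 0 || max(data) > 255) {
    stopf("gray_image intensities must be in [0.0, 255.0]", class = "aminoblot_domain_error")
  }
  structure(data, class = "gray_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d, 8-bit RGB>\n", d[1], d[2]))
  invisible(x)
}

#' @export
print.gray_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<gray_image %d x %d, intensity range [%.2f, %.2f]>\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

#' Weighted RGB intensity of a pixel
#'
#' The scalar luminance definition used everywhere in this package:
#' `0.30 R + 0.59 G + 0.11 B`, the weighted-channel average that common
#' image-analysis tools apply when converting color scans to grayscale.
#' The weights sum to 1, so the result stays in \[0, 255\].
#'
#' @param r,g,b channel values in \[0, 255\]; vectorized.
#' @return real-valued intensity in \[0, 255\].
#' @examples
#' weighted_intensity(255, 255, 255) # 255
#' weighted_intensity(100, 0, 0)     # 30
#' @export
weighted_intensity <- function(r, g, b) {
  v <- c(r, g, b)
  if (anyNA(v) || min(v) < 0 || max(v) > 255) {
    stopf("channel values must be in [0, 255]", class = "aminoblot_domain_error")
  }
  0.30 * r + 0.59 * g + 0.11 * b
}

#' Convert an RGB image to weighted-intensity grayscale
#'
#' Applies [weighted_intensity()] per pixel. One grayscale definition serves
#' the whole pipeline (desaturation for overlays and the intensity entering
#' calibration), so measured intensities and rendered overlays are always on
#' the same scale.
#'
#' @param image an [rgb_image()].
#' @return a [gray_image()] of the same dimensions.
#' @export
to_gray <- function(image) {
  if (!inherits(image, "rgb_image")) {
    stopf("to_gray expects an rgb_image", class = "aminoblot_shape_error")
  }
  g <- 0.30 * image[, , 1] + 0.59 * image[, , 2] + 0.11 * image[, , 3]
  gray_image(g)
}

#' Multiply-blend two images
#'
#' Standard multiply compositing: per channel, `out = round(base * layer /
#' 255)`. Multiplying never brightens, so dark blot signal survives on top
#' of a bright scan. A `gray_image` base is broadcast to three channels
#' first (with export rounding). The operation is symmetric in its
#' arguments.
#'
#' @param base an [rgb_image()] or [gray_image()].
#' @param layer an [rgb_image()] of identical height/width.
#' @return an [rgb_image()].
#' @export
multiply_blend <- function(base, layer) {
  if (inherits(base, "gray_image")) base <- gray_to_rgb(base)
  if (!inherits(base, "rgb_image") || !inherits(layer, "rgb_image")) {
    stopf("multiply_blend expects rgb_image (or gray_image base) inputs",
          class = "aminoblot_shape_error")
  }
  if (!identical(dim(base)[1:2], dim(layer)[1:2])) {
    stopf("multiply_blend: dimension mismatch (%d x %d vs %d x %d)",
          dim(base)[1], dim(base)[2], dim(layer)[1], dim(layer)[2],
          class = "aminoblot_shape_error")
  }
  out <- round_half_away(unclass(base) * unclass(layer) / 255)
  rgb_image(out)
}

#' Broadcast a grayscale image to an 8-bit RGB image
#'
#' Intensities are quantized with the export rounding rule
#' (round half away from zero).
#'
#' @param image a [gray_image()].
#' @return an [rgb_image()] with three identical channels.
#' @export
gray_to_rgb <- function(image) {
  if (!inherits(image, "gray_image")) {
    stopf("gray_to_rgb expects a gray_image", class = "aminoblot_shape_error")
  }
  q <- round_half_away(unclass(image))
  rgb_image(array(rep(q, 3L), dim = c(dim(image), 3L)))
}
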