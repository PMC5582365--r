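# Concentration heatmaps and root/blot overlay composition.

#' Standardized concentration color scale
#'
#' Linear mapping from concentration to a named gradient. The default is
#' the perceptually uniform "viridis" ramp with 256 stops spanning 0 mM to
#' the top standard (4.71 mM), so renderings from different papers are
#' directly comparable. A legend bar is drawn by default: the palette is a
#' package choice, so renderings must stay self-describing.
#'
#' @param min_conc,max_conc scale bounds in mM; `min_conc < max_conc`.
#' @param colormap palette name understood by [grDevices::hcl.colors()].
#' @param n_stops number of ordered color stops (>= 2; default 256).
#' @param legend draw a legend bar on rendered images? Default `TRUE`.
#' @param ticks concentrations marked on the legend (default the three
#'   calibration standards).
#' @return a `color_scale` object with an `n_stops x 3` integer stop matrix.
#' @export
color_scale <- function(min_conc = 0, max_conc = 4.71, colormap = "viridis",
                        n_stops = 256L, legend = TRUE,
                        ticks = c(1.71, 3.41, 4.71)) {
  if (!is.finite(min_conc) || !is.finite(max_conc) || min_conc >= max_conc) {
    stopf("color scale needs min_conc < max_conc", class = "aminoblot_domain_error")
  }
  if (n_stops < 2L) stopf("color scale needs >= 2 stops", class = "aminoblot_domain_error")
  stops <- t(grDevices::col2rgb(grDevices::hcl.colors(n_stops, palette = colormap)))
  colnames(stops) <- c("r", "g", "b")
  structure(list(min_conc = min_conc, max_conc = max_conc, colormap = colormap,
                 stops = stops, legend = legend,
                 ticks = ticks[ticks >= min_conc & ticks <= max_conc]),
            class = "color_scale")
}

#' Per-pixel concentration map from a grayscale blot image
#'
#' Applies the inverse calibration [intensity_to_conc()] to every pixel and
#' clamps the result to the scale bounds. The result carries the scale and
#' the calibration parameters it was derived from (provenance), so a
#' rendering can always be traced to its model.
#'
#' @param image a [gray_image()] of the developed blot.
#' @param model a `calibration_model`.
#' @param scale a [color_scale()]; defaults to `[0, model$clamp_max]`.
#' @return a `concentration_map`: `conc` (mM matrix), `scale`, `provenance`.
#' @export
concentration_map <- function(image, model, scale = NULL) {
  if (!inherits(image, "gray_image")) {
    stopf("concentration_map expects a gray_image", class = "aminoblot_shape_error")
  }
  scale <- scale %||% color_scale(min_conc = 0, max_conc = model$clamp_max)
  conc <- intensity_to_conc(model, unclass(image), clamp = FALSE)
  conc <- pmin(pmax(conc, scale$min_conc), scale$max_conc)
  structure(list(conc = conc, scale = scale,
                 provenance = list(slope = model$slope, intercept = model$intercept,
                                   n = model$n, level = model$level,
                                   clamp_max = model$clamp_max)),
            class = "concentration_map")
}

#' @export
print.concentration_map <- function(x, ...) {
  cat(sprintf("<concentration_map %d x %d, %.3f-%.3f mM (scale [%g, %g])>\n",
              nrow(x$conc), ncol(x$conc), min(x$conc), max(x$conc),
              x$scale$min_conc, x$scale$max_conc))
  invisible(x)
}

# 3x5 bitmap glyphs for legend tick labels (digits and decimal point).
.legend_font <- list(
  "0" = c(7, 5, 5, 5, 7), "1" = c(2, 6, 2, 2, 7), "2" = c(7, 1, 7, 4, 7),
  "3" = c(7, 1, 7, 1, 7), "4" = c(5, 5, 7, 1, 1), "5" = c(7, 4, 7, 1, 7),
  "6" = c(7, 4, 7, 5, 7), "7" = c(7, 1, 2, 2, 2), "8" = c(7, 5, 7, 5, 7),
  "9" = c(7, 5, 7, 1, 7), "." = c(0, 0, 0, 0, 2)
)

draw_text <- function(canvas, row, col, text, value = 0) {
  # stamp 3x5 glyphs into a numeric matrix; row/col 1-based top-left
  for (ch in strsplit(text, "")[[1]]) {
    glyph <- .legend_font[[ch]]
    if (!is.null(glyph)) {
      for (gr in 1:5) {
        bits <- bitwAnd(bitwShiftR(glyph[gr], 2:0), 1L) == 1L
        rr <- row + gr - 1L
        cc <- col + which(bits) - 1L
        keep <- rr >= 1 & rr <= nrow(canvas) & cc >= 1 & cc <= ncol(canvas)
        if (rr >= 1 && rr <= nrow(canvas) && any(keep)) {
          canvas[rr, cc[keep]] <- value
        }
      }
    }
    col <- col + 4L
  }
  canvas
}

legend_panel <- function(scale, height) {
  bar_w <- 12L; gap <- 3L; label_w <- 18L; margin <- 4L
  width <- margin + bar_w + gap + label_w + margin
  panel <- array(255, dim = c(height, width, 3))
  top <- margin; bottom <- height - margin
  n <- nrow(scale$stops)
  rows <- top:bottom
  # max_conc at the top of the bar
  frac <- (bottom - rows) / (bottom - top)
  idx <- 1L + round(frac * (n - 1L))
  for (ch in 1:3) {
    panel[rows, margin + seq_len(bar_w), ch] <- scale$stops[idx, ch]
  }
  lab <- matrix(255, height, label_w + gap)
  for (tk in scale$ticks) {
    f <- (tk - scale$min_conc) / (scale$max_conc - scale$min_conc)
    r <- round(bottom - f * (bottom - top))
    lab[r, seq_len(gap)] <- 0 # tick mark
    lab <- draw_text(lab, r - 2L, gap + 2L, format(tk), value = 0)
  }
  for (ch in 1:3) {
    panel[, margin + bar_w + seq_len(gap + label_w), ch] <- lab
  }
  panel
}

#' Render a concentration map as a false-color image
#'
#' Concentration maps linearly onto the scale's ordered color stops;
#' `min_conc` takes the first stop, `max_conc` the last. When the scale
#' requests a legend, a color bar with tick marks and labels at the scale's
#' tick concentrations is appended on the right. Deterministic: identical
#' inputs give bit-identical images.
#'
#' @param map a [concentration_map()].
#' @param scale optional [color_scale()] override (default: the map's own).
#' @return an [rgb_image()].
#' @export
render_heatmap <- function(map, scale = NULL) {
  scale <- scale %||% map$scale
  conc <- pmin(pmax(map$conc, scale$min_conc), scale$max_conc)
  n <- nrow(scale$stops)
  idx <- 1L + round((conc - scale$min_conc) / (scale$max_conc - scale$min_conc) * (n - 1L))
  h <- nrow(conc); w <- ncol(conc)
  arr <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) arr[, , ch] <- matrix(scale$stops[idx, ch], h, w)
  if (isTRUE(scale$legend)) {
    leg <- legend_panel(scale, h)
    out <- array(0, dim = c(h, w + dim(leg)[2], 3))
    out[, seq_len(w), ] <- arr
    out[, w + seq_len(dim(leg)[2]), ] <- leg
    arr <- out
  }
  rgb_image(arr)
}

#' Decode a heatmap color back to a concentration
#'
#' Nearest-stop inverse of [render_heatmap()], mainly for round-trip
#' verification; accurate to one colormap quantization step.
#'
#' @param rgb length-3 channel vector (or n x 3 matrix).
#' @param scale the [color_scale()] used for rendering.
#' @return concentration(s) in mM.
#' @export
decode_heatmap_color <- function(rgb, scale) {
  rgb <- matrix(rgb, ncol = 3)
  n <- nrow(scale$stops)
  conc_at <- scale$min_conc + (seq_len(n) - 1) / (n - 1) * (scale$max_conc - scale$min_conc)
  apply(rgb, 1, function(px) {
    d2 <- rowSums(sweep(scale$stops, 2, px)^2)
    conc_at[which.min(d2)]
  })
}

#' Overlay a blot image on a root scan with multiply blending
#'
#' Mirrors the manual workflow: the root scan is desaturated, the blot
#' layer is rigidly moved into register (user-supplied integer offset plus
#' rotation about the blot center, nearest-neighbor resampling so no new
#' intensities are invented) and composited with a multiply blend. Output
#' pixels the transformed blot does not reach keep the grayscale root
#' unchanged (the blot is treated as white there).
#'
#' @param root an [rgb_image()] (or [gray_image()]) of the scanned roots.
#' @param blot an [rgb_image()] of the developed sensor paper.
#' @param offset `c(rows, cols)` translation of the blot in the root frame.
#' @param rotation rotation of the blot in degrees, counter-clockwise,
#'   about the blot center.
#' @return an [rgb_image()] with the root scan's dimensions.
#' @export
overlay <- function(root, blot, offset = c(0, 0), rotation = 0) {
  base <- if (inherits(root, "gray_image")) gray_to_rgb(root) else gray_to_rgb(to_gray(root))
  if (!inherits(blot, "rgb_image")) {
    stopf("blot must be an rgb_image", class = "aminoblot_shape_error")
  }
  h <- dim(base)[1]; w <- dim(base)[2]
  bh <- dim(blot)[1]; bw <- dim(blot)[2]
  theta <- rotation * pi / 180
  cb <- c((bh - 1) / 2, (bw - 1) / 2) # blot center, 0-based
  # root-frame pixel grid (0-based)
  rr <- matrix(0:(h - 1), h, w)
  cc <- matrix(0:(w - 1), h, w, byrow = TRUE)
  # invert: blot was rotated about its center then translated by offset
  ry <- rr - offset[1] - cb[1]
  rx <- cc - offset[2] - cb[2]
  sr <- round(cos(theta) * ry + sin(theta) * rx + cb[1]) + 1
  sc <- round(-sin(theta) * ry + cos(theta) * rx + cb[2]) + 1
  inside <- sr >= 1 & sr <= bh & sc >= 1 & sc <= bw
  if (!any(inside)) {
    stopf("blot and root do not overlap after the supplied transform",
          class = "aminoblot_alignment_error")
  }
  layer <- array(255, dim = c(h, w, 3))
  src <- cbind(sr[inside], sc[inside])
  for (ch in 1:3) {
    plane <- matrix(255, h, w)
    plane[inside] <- unclass(blot)[, , ch][src]
    layer[, , ch] <- plane
  }
  multiply_blend(base, rgb_image(layer))
}
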