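# Spot segmentation: seeded flood fill (the algorithmic stand-in for an
# interactive magic-wand selection) and calibration-grid detection.
#
# Pixel coordinates at all public interfaces are 0-based with the origin at
# the top-left, matching image conventions; internal matrix indexing is the
# usual R 1-based form.

shift_logical <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  if (length(rs) && length(cs)) {
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  }
  out
}

neighbor_offsets <- function(connectivity) {
  if (connectivity == 4L) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else if (connectivity == 8L) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  } else {
    stopf("connectivity must be 4 or 8", class = "aminoblot_domain_error")
  }
}

# Connected component of `mask` containing (row, col) [1-based], by
# vectorized frontier dilation.
flood_component <- function(mask, row, col, connectivity = 8L) {
  offs <- neighbor_offsets(connectivity)
  visited <- matrix(FALSE, nrow(mask), ncol(mask))
  visited[row, col] <- TRUE
  frontier <- visited
  repeat {
    grown <- Reduce(`|`, lapply(offs, function(o) shift_logical(frontier, o[1], o[2])))
    new <- grown & mask & !visited
    if (!any(new)) break
    visited <- visited | new
    frontier <- new
  }
  visited
}

make_spot <- function(member, image) {
  idx <- which(member, arr.ind = TRUE)
  intens <- unclass(image)[member]
  structure(list(
    pixels = cbind(row = idx[, 1] - 1L, col = idx[, 2] - 1L),
    centroid = c(row = mean(idx[, 1]) - 1, col = mean(idx[, 2]) - 1),
    area = nrow(idx),
    mean_intensity = mean(intens),
    touches_border = any(idx[, 1] == 1L | idx[, 1] == nrow(member) |
                           idx[, 2] == 1L | idx[, 2] == ncol(member))
  ), class = "spot")
}

#' @export
print.spot <- function(x, ...) {
  cat(sprintf("<spot: area %d px, centroid (%.1f, %.1f), mean intensity %.2f%s>\n",
              x$area, x$centroid[1], x$centroid[2], x$mean_intensity,
              if (x$touches_border) ", touches border" else ""))
  invisible(x)
}

#' Magic-wand selection by seeded flood fill
#'
#' Grows the maximal connected region around `seed` whose intensities stay
#' within `tolerance` of the seed pixel's value. Deviation is measured from
#' the seed (not a running region mean), the simplest reproducible contract
#' and the behavior of common wand tools.
#'
#' @param image a [gray_image()].
#' @param seed `c(row, col)` 0-based coordinates of the seed pixel.
#' @param tolerance maximum absolute intensity deviation from the seed
#'   value, >= 0 (default 20 intensity units).
#' @param connectivity 4 or 8 (default 8).
#' @return a `spot` object: `pixels` (0-based coordinates), `centroid`,
#'   `area`, `mean_intensity`, `touches_border`.
#' @export
flood_select <- function(image, seed, tolerance = 20, connectivity = 8L) {
  if (!inherits(image, "gray_image")) {
    stopf("flood_select expects a gray_image", class = "aminoblot_shape_error")
  }
  if (length(seed) != 2L || anyNA(seed)) {
    stopf("seed must be c(row, col)", class = "aminoblot_coordinate_error")
  }
  r <- as.integer(seed[1]) + 1L
  c <- as.integer(seed[2]) + 1L
  if (r < 1L || r > nrow(image) || c < 1L || c > ncol(image)) {
    stopf("seed (%d, %d) is outside the %d x %d image", seed[1], seed[2],
          nrow(image), ncol(image), class = "aminoblot_coordinate_error")
  }
  if (tolerance < 0) {
    stopf("tolerance must be >= 0", class = "aminoblot_domain_error")
  }
  mask <- abs(unclass(image) - unclass(image)[r, c]) <= tolerance
  member <- flood_component(mask, r, c, as.integer(connectivity))
  make_spot(member, image)
}

#' Mean intensity over a spot's pixels
#'
#' @param spot a `spot` object (or anything with a 0-based `pixels` matrix).
#' @param image a [gray_image()] containing all spot pixels.
#' @return arithmetic mean intensity.
#' @export
spot_mean_intensity <- function(spot, image) {
  px <- spot$pixels
  if (is.null(px) || nrow(px) == 0L) {
    stopf("spot has no pixels", class = "aminoblot_domain_error")
  }
  if (any(px[, 1] < 0L) || any(px[, 2] < 0L) ||
      any(px[, 1] >= nrow(image)) || any(px[, 2] >= ncol(image))) {
    stopf("spot pixels fall outside the image", class = "aminoblot_coordinate_error")
  }
  mean(unclass(image)[cbind(px[, 1] + 1L, px[, 2] + 1L)])
}

#' Calibration-grid geometry
#'
#' Describes the printed grid of indicator cells spotted with standards:
#' a `rows x cols` array of (roughly circular) spots with centers `pitch`
#' pixels apart, the first center at `origin` (0-based row, col).
#'
#' @param rows,cols grid shape (default 3 x 3, the printed calibration grid).
#' @param pitch center-to-center spacing in pixels; must exceed twice
#'   `expected_radius` so neighboring spots cannot merge.
#' @param origin `c(row, col)` of the top-left spot center, 0-based.
#' @param expected_radius nominal developed-spot radius in pixels.
#' @return a `grid_spec` object.
#' @export
grid_spec <- function(rows = 3L, cols = 3L, pitch, origin, expected_radius) {
  if (rows < 1L || cols < 1L) stopf("grid must have rows, cols >= 1",
                                    class = "aminoblot_domain_error")
  if (pitch <= 2 * expected_radius) {
    stopf("pitch (%s) must exceed 2 * expected_radius (%s)", pitch,
          2 * expected_radius, class = "aminoblot_domain_error")
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pitch = pitch, origin = origin,
                 expected_radius = expected_radius),
            class = "grid_spec")
}

grid_centers <- function(grid) {
  # 0-based centers, row-major order
  cells <- expand.grid(col = seq_len(grid$cols), row = seq_len(grid$rows))
  data.frame(cell_row = cells$row, cell_col = cells$col,
             row = grid$origin[1] + (cells$row - 1) * grid$pitch,
             col = grid$origin[2] + (cells$col - 1) * grid$pitch)
}

#' Otsu's threshold of a grayscale image
#'
#' Maximizes between-class variance on the 256-bin intensity histogram.
#' Returns the boundary value: pixels strictly below it belong to the dark
#' class.
#'
#' @param image a [gray_image()].
#' @return numeric threshold in \[0, 255\].
#' @export
otsu_threshold <- function(image) {
  v <- round_half_away(as.vector(unclass(image)))
  counts <- as.numeric(tabulate(v + 1L, nbins = 256L))
  total <- sum(counts)
  levels <- 0:255
  w0 <- cumsum(counts)
  sum0 <- cumsum(counts * levels)
  mu_total <- sum0[256]
  w1 <- total - w0
  between <- ifelse(w0 > 0 & w1 > 0,
                    (mu_total * w0 - total * sum0)^2 / (w0 * w1), 0)
  t_star <- which.max(between) - 1L # dark class: <= t_star
  t_star + 0.5
}

# Background-mode threshold: modal rounded intensity minus 10% (>= 8 units).
background_threshold <- function(image) {
  v <- round_half_away(as.vector(unclass(image)))
  counts <- tabulate(v + 1L, nbins = 256L)
  mode_int <- which.max(counts) - 1L
  mode_int - max(8, 0.1 * mode_int)
}

#' Locate and measure the calibration grid
#'
#' Automates the manual spot selection: global threshold -> connected
#' components -> area filter (components between 0.25x and 4x the expected
#' disk area) -> assignment of each surviving component to the nearest
#' expected grid center within `pitch / 2`.
#'
#' Threshold policies: the default `"background"` takes the modal rounded
#' intensity (blot papers are mostly background) and thresholds 10% (at
#' least 8 units) below it — robust when faint spots would otherwise be
#' absorbed into the background class. `"otsu"` maximizes between-class
#' variance, appropriate for strongly bimodal images; a numeric value fixes
#' the boundary directly. Pixels strictly below the boundary are
#' foreground.
#'
#' @param image a [gray_image()] containing a developed grid.
#' @param grid a [grid_spec()].
#' @param threshold `"background"` (default), `"otsu"`, or a fixed numeric
#'   boundary.
#' @param connectivity 4 or 8 (default 8) for component labeling.
#' @return list of `spot` objects of length `rows * cols` in row-major
#'   order.
#' @export
detect_grid <- function(image, grid, threshold = "background", connectivity = 8L) {
  if (!inherits(image, "gray_image")) {
    stopf("detect_grid expects a gray_image", class = "aminoblot_shape_error")
  }
  thr <- if (identical(threshold, "background")) {
    background_threshold(image)
  } else if (identical(threshold, "otsu")) {
    otsu_threshold(image)
  } else {
    as.numeric(threshold)
  }
  mask <- unclass(image) < thr
  expected_area <- pi * grid$expected_radius^2
  comps <- list()
  remaining <- mask
  while (any(remaining)) {
    first <- which(remaining)[1]
    r <- (first - 1L) %% nrow(mask) + 1L
    c <- (first - 1L) %/% nrow(mask) + 1L
    member <- flood_component(remaining, r, c, as.integer(connectivity))
    remaining <- remaining & !member
    area <- sum(member)
    if (area >= 0.25 * expected_area && area <= 4 * expected_area) {
      comps[[length(comps) + 1L]] <- make_spot(member, image)
    }
  }
  centers <- grid_centers(grid)
  spots <- vector("list", nrow(centers))
  missing <- character(0)
  claimed <- logical(length(comps))
  for (i in seq_len(nrow(centers))) {
    if (length(comps)) {
      d <- vapply(comps, function(s) {
        sqrt((s$centroid[1] - centers$row[i])^2 + (s$centroid[2] - centers$col[i])^2)
      }, numeric(1))
      d[claimed] <- Inf
      j <- which.min(d)
    } else {
      j <- integer(0)
    }
    if (length(comps) == 0L || d[j] > grid$pitch / 2) {
      missing <- c(missing, sprintf("r%dc%d", centers$cell_row[i], centers$cell_col[i]))
    } else {
      claimed[j] <- TRUE
      spots[[i]] <- comps[[j]]
    }
  }
  if (length(missing)) {
    stopf("grid detection failed: no spot found for cell(s) %s",
          paste(missing, collapse = ", "), class = "aminoblot_detection_error")
  }
  spots
}

#' Tabulate detected grid spots as a tidy spot table
#'
#' One row per grid cell in row-major order, matching the CSV schema used
#' by the calibration pipeline. When `standards` is supplied, row `i` of
#' the grid is assigned `standards[(i - 1) %% length(standards) + 1]`.
#'
#' @param spots list of `spot` objects from [detect_grid()].
#' @param grid the [grid_spec()] used for detection.
#' @param paper_id identifier recorded in the table.
#' @param standards optional standard concentrations (mM) by grid row.
#' @return data.frame with columns `paper_id`, `grid_cell`,
#'   `concentration_mM`, `mean_intensity`, `area_px`, `centroid_row`,
#'   `centroid_col`, `touches_border`.
#' @export
spot_table <- function(spots, grid, paper_id = "paper", standards = NULL) {
  centers <- grid_centers(grid)
  conc <- if (is.null(standards)) NA_real_ else
    standards[(centers$cell_row - 1) %% length(standards) + 1]
  data.frame(
    paper_id = paper_id,
    grid_cell = sprintf("r%dc%d", centers$cell_row, centers$cell_col),
    concentration_mM = conc,
    mean_intensity = vapply(spots, `[[`, numeric(1), "mean_intensity"),
    area_px = vapply(spots, `[[`, numeric(1), "area"),
    centroid_row = vapply(spots, function(s) unname(s$centroid[1]), numeric(1)),
    centroid_col = vapply(spots, function(s) unname(s$centroid[2]), numeric(1)),
    touches_border = vapply(spots, `[[`, logical(1), "touches_border"),
    stringsAsFactors = FALSE
  )
}
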