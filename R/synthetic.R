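# Ground-truthed synthetic fixtures: calibration spot batches, blot paper
# images (grid + root trace) and partner root scans. Every generator is a
# pure function of its parameters and seed, and serializes its truth so
# downstream stages can be verified without a scanner.

#' Synthetic calibration-spot batch
#'
#' Spot mean intensities are drawn from the generating line
#' `slope * conc + intercept` plus Gaussian noise. Designated outlier
#' papers receive an additive intensity shift at one designated
#' concentration for `n_spots` of their replicates, emulating sheets that
#' developed atypically.
#'
#' @param n_papers sheets in the batch (>= 1).
#' @param standards standard concentrations, mM.
#' @param replicates spots per standard per paper (>= 1).
#' @param noise_sd Gaussian intensity noise SD.
#' @param outlier_papers either a character vector of paper ids (defaults:
#'   shift +60 at the middle standard, all replicates), or a list of
#'   entries `list(paper_id =, concentration =, shift =, n_spots =)`.
#' @param slope,intercept generating calibration line (defaults: the
#'   reference line, slope -20.98, intercept 241.71).
#' @param seed RNG seed.
#' @return list with `spots` (data.frame in the spot-table schema) and
#'   `truth` (generating parameters and the normalized outlier spec).
#' @export
make_calibration_batch <- function(n_papers = 10L,
                                   standards = c(1.71, 3.41, 4.71),
                                   replicates = 3L, noise_sd = 3,
                                   outlier_papers = NULL,
                                   slope = -20.98, intercept = 241.71,
                                   seed = 1L) {
  if (n_papers < 1L || replicates < 1L) {
    stopf("need n_papers >= 1 and replicates >= 1", class = "aminoblot_domain_error")
  }
  papers <- sprintf("P%02d", seq_len(n_papers))
  outliers <- normalize_outlier_spec(outlier_papers, papers, standards, replicates)
  with_seed(seed, {
    grid <- expand.grid(rep = seq_len(replicates),
                        std = seq_along(standards),
                        paper = seq_len(n_papers))
    conc <- standards[grid$std]
    intensity <- slope * conc + intercept +
      if (noise_sd > 0) stats::rnorm(nrow(grid), 0, noise_sd) else 0
    for (o in outliers) {
      sel <- papers[grid$paper] == o$paper_id & conc == o$concentration &
        grid$rep <= o$n_spots
      intensity[sel] <- intensity[sel] + o$shift
    }
    spots <- data.frame(
      paper_id = papers[grid$paper],
      grid_cell = sprintf("r%dc%d", grid$std, grid$rep),
      concentration_mM = conc,
      mean_intensity = pmin(pmax(intensity, 0), 255),
      area_px = round(pi * 10^2),
      centroid_row = 24 + (grid$std - 1) * 34,
      centroid_col = 24 + (grid$rep - 1) * 34,
      touches_border = FALSE,
      stringsAsFactors = FALSE
    )
    list(spots = spots,
         truth = list(slope = slope, intercept = intercept,
                      standards = standards, replicates = replicates,
                      noise_sd = noise_sd, outliers = outliers,
                      outlier_paper_ids = vapply(outliers, `[[`, character(1), "paper_id"),
                      seed = seed))
  })
}

normalize_outlier_spec <- function(spec, papers, standards, replicates) {
  if (is.null(spec)) return(list())
  if (is.character(spec)) {
    spec <- lapply(spec, function(p) list(paper_id = p))
  }
  lapply(spec, function(o) {
    o$concentration <- o$concentration %||% standards[ceiling(length(standards) / 2)]
    o$shift <- o$shift %||% 60
    o$n_spots <- o$n_spots %||% replicates
    if (!o$paper_id %in% papers) {
      stopf("outlier spec names unknown paper %s", o$paper_id,
            class = "aminoblot_spec_error")
    }
    if (!o$concentration %in% standards) {
      stopf("outlier spec names unknown concentration %s", o$concentration,
            class = "aminoblot_spec_error")
    }
    o
  })
}

# Find an integer purple-ish (R, G, B) whose weighted intensity
# (30R + 59G + 11B)/100 is as close as possible to the target (exact
# whenever the 0.01 grid point is representable, which holds everywhere
# except within ~0.3 units of pure white and near pure black). The search
# walks G downward from just above the target; for fixed G the diophantine
# part 30R + 11B = 100*target - 59G is solved by residues mod 30.
# Deterministic and non-recursive.
best_purple_triple <- function(target) {
  tt <- min(max(round(target, 2), 0), 255)
  T0 <- round(tt * 100)
  best <- NULL
  best_err <- Inf
  for (G in seq(min(255L, floor(tt) + 1L), max(0L, floor(tt) - 40L), by = -1L)) {
    rhs <- T0 - 59L * G
    if (rhs < 0L) next
    if (rhs > 10455L) break # rhs only grows as G decreases
    b0 <- (11L * rhs) %% 30L
    bs <- seq.int(b0, 255L, by = 30L)
    rs <- (rhs - 11L * bs) / 30L
    ok <- rs >= 0L & rs <= 255L
    if (!any(ok)) next
    bs <- bs[ok]; rs <- rs[ok]
    # prefer R, B >= G (purple hue) and balanced R vs B
    pref <- (bs >= G) + (rs >= G)
    score <- -pref * 1000 + abs(rs - bs)
    j <- which.min(score)
    cand <- c(rs[j], G, bs[j])
    err <- abs((30 * cand[1] + 59 * cand[2] + 11 * cand[3]) / 100 - target)
    if (err < best_err - 1e-12) {
      best <- cand
      best_err <- err
    }
    if (pref[j] == 2L) break # exact and purple: done
  }
  if (is.null(best)) {
    # unrepresentable extremes (within ~0.3 of pure white/black): fall back
    # to the nearest neutral gray, off by at most ~0.5 intensity units
    g <- round_half_away(tt)
    best <- c(g, g, g)
  }
  best
}

# Vectorized purple synthesis over a gray target matrix.
purple_from_gray <- function(gray) {
  tt <- round(gray, 2)
  uv <- sort(unique(as.vector(tt)))
  trip <- vapply(uv, best_purple_triple, numeric(3))
  idx <- match(tt, uv)
  h <- nrow(gray); w <- ncol(gray)
  arr <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) arr[, , ch] <- matrix(trip[ch, idx], h, w)
  rgb_image(arr)
}

# Distance from every pixel to a polyline, plus interpolated arc-length
# fraction of the nearest point. points: n x 2 (row, col), 0-based.
polyline_field <- function(h, w, points) {
  rr <- matrix(0:(h - 1), h, w)
  cc <- matrix(0:(w - 1), h, w, byrow = TRUE)
  nseg <- nrow(points) - 1L
  seg_len <- sqrt(diff(points[, 1])^2 + diff(points[, 2])^2)
  cum <- c(0, cumsum(seg_len))
  total <- cum[nseg + 1L]
  dist <- matrix(Inf, h, w)
  sfrac <- matrix(0, h, w)
  for (k in seq_len(nseg)) {
    a <- points[k, ]; b <- points[k + 1L, ]
    vy <- b[1] - a[1]; vx <- b[2] - a[2]
    L2 <- vy^2 + vx^2
    t <- if (L2 > 0) pmin(pmax(((rr - a[1]) * vy + (cc - a[2]) * vx) / L2, 0), 1) else 0
    dk <- sqrt((rr - (a[1] + t * vy))^2 + (cc - (a[2] + t * vx))^2)
    closer <- dk < dist
    dist[closer] <- dk[closer]
    sfrac[closer] <- (cum[k] + t[closer] * seg_len[k]) / total
  }
  list(dist = dist, sfrac = sfrac)
}

default_blot_grid <- function() {
  grid_spec(rows = 3L, cols = 3L, pitch = 34, origin = c(24, 24),
            expected_radius = 10)
}

#' Synthetic blot-paper image with ground truth
#'
#' Draws a bright background near the calibration intercept, dark grid
#' disks whose intensities come from the generating line at each standard
#' (grid row i carries standard i), and optionally a root-shaped band with
#' Gaussian cross-section whose centerline intensity follows a
#' per-arc-length concentration profile. The purple tint is synthesized so
#' the weighted RGB intensity equals the gray target (exactly, away from
#' pure white); the gray contract, not the hue, is what downstream code
#' consumes.
#'
#' @param width,height image size in pixels.
#' @param background_intensity background gray level (default: the
#'   generating intercept).
#' @param grid a [grid_spec()] (default 3 x 3, pitch 34, radius 10 at
#'   origin (24, 24)).
#' @param standards standard concentrations by grid row, mM.
#' @param slope,intercept generating calibration line.
#' @param trace optional n x 2 (row, col) polyline for the root band.
#' @param profile concentration profile along the trace, mM: a single
#'   number or a vector linearly interpolated over normalized arc length.
#' @param band_sigma Gaussian cross-section SD of the band, pixels.
#' @param noise_sd per-pixel Gaussian intensity noise SD.
#' @param seed RNG seed.
#' @return list with `image` (an [rgb_image()]) and `truth` (gray target,
#'   per-pixel concentration map, per-cell spot records with disk masks,
#'   and all generating parameters).
#' @export
make_blot_image <- function(width = 220L, height = 300L,
                            background_intensity = NULL,
                            grid = default_blot_grid(),
                            standards = c(1.71, 3.41, 4.71),
                            slope = -20.98, intercept = 241.71,
                            trace = NULL, profile = NULL,
                            band_sigma = 2.5, noise_sd = 0, seed = 1L) {
  bg <- background_intensity %||% intercept
  h <- as.integer(height); w <- as.integer(width)
  centers <- grid_centers(grid)
  r_spot <- grid$expected_radius
  if (any(centers$row - r_spot < 0 | centers$row + r_spot > h - 1 |
          centers$col - r_spot < 0 | centers$col + r_spot > w - 1)) {
    stopf("grid geometry does not fit inside a %d x %d image", h, w,
          class = "aminoblot_layout_error")
  }
  gray <- matrix(bg, h, w)
  rr <- matrix(0:(h - 1), h, w)
  cc <- matrix(0:(w - 1), h, w, byrow = TRUE)
  cells <- vector("list", nrow(centers))
  grid_mask <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(centers))) {
    conc <- standards[(centers$cell_row[i] - 1) %% length(standards) + 1]
    target <- slope * conc + intercept
    mask <- (rr - centers$row[i])^2 + (cc - centers$col[i])^2 <= r_spot^2
    gray[mask] <- target
    grid_mask <- grid_mask | mask
    cells[[i]] <- list(cell = sprintf("r%dc%d", centers$cell_row[i], centers$cell_col[i]),
                       row = centers$row[i], col = centers$col[i],
                       concentration = conc, target_intensity = target,
                       mask = which(mask))
  }
  band_mask <- NULL
  if (!is.null(trace)) {
    trace <- as.matrix(trace)
    if (any(trace[, 1] < 0 | trace[, 1] > h - 1 | trace[, 2] < 0 | trace[, 2] > w - 1)) {
      stopf("trace geometry does not fit inside a %d x %d image", h, w,
            class = "aminoblot_layout_error")
    }
    fld <- polyline_field(h, w, trace)
    reach <- fld$dist < 4 * band_sigma
    if (any(reach & grid_mask)) {
      stopf("root trace band overlaps the calibration grid",
            class = "aminoblot_layout_error")
    }
    prof <- profile %||% 0
    conc_s <- if (length(prof) == 1L) rep(prof, sum(reach)) else {
      stats::approx(seq(0, 1, length.out = length(prof)), prof,
                    xout = fld$sfrac[reach], rule = 2)$y
    }
    center_int <- slope * conc_s + intercept
    weight <- exp(-fld$dist[reach]^2 / (2 * band_sigma^2))
    gray[reach] <- bg + (center_int - bg) * weight
    band_mask <- reach
  }
  truth_seedless <- gray
  if (noise_sd > 0) {
    gray <- with_seed(seed, gray + stats::rnorm(length(gray), 0, noise_sd))
  }
  gray <- pmin(pmax(gray, 0), 255)
  img <- purple_from_gray(gray)
  achieved <- to_gray(img)
  conc_map <- intensity_to_conc(
    structure(list(slope = slope, intercept = intercept,
                   clamp_max = max(standards)), class = "calibration_model"),
    unclass(achieved))
  list(image = img,
       truth = list(gray_target = truth_seedless,
                    gray_achieved = unclass(achieved),
                    conc_map = conc_map,
                    cells = cells, grid = grid, standards = standards,
                    slope = slope, intercept = intercept,
                    background = bg, trace = trace, profile = profile,
                    band_sigma = band_sigma, band_mask = band_mask,
                    noise_sd = noise_sd, seed = seed))
}

#' Synthetic root-scan image
#'
#' Partner image for overlay tests: blue germination-paper background with
#' a pale root band along the supplied trace. Deterministic per seed.
#'
#' @param trace n x 2 (row, col) polyline, 0-based.
#' @param width,height image size in pixels.
#' @param band_sigma Gaussian cross-section SD of the root band, pixels.
#' @param noise_sd per-channel Gaussian noise SD (default 0).
#' @param seed RNG seed.
#' @return an [rgb_image()].
#' @export
make_root_scan <- function(trace, width = 220L, height = 300L,
                           band_sigma = 3, noise_sd = 0, seed = 1L) {
  trace <- as.matrix(trace)
  h <- as.integer(height); w <- as.integer(width)
  if (any(trace[, 1] < 0 | trace[, 1] > h - 1 | trace[, 2] < 0 | trace[, 2] > w - 1)) {
    stopf("trace geometry does not fit inside a %d x %d image", h, w,
          class = "aminoblot_layout_error")
  }
  fld <- polyline_field(h, w, trace)
  weight <- exp(-fld$dist^2 / (2 * band_sigma^2))
  bg <- c(70, 90, 165)
  root <- c(235, 230, 218)
  arr <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) arr[, , ch] <- bg[ch] + (root[ch] - bg[ch]) * weight
  if (noise_sd > 0) {
    arr <- with_seed(seed, arr + stats::rnorm(length(arr), 0, noise_sd))
  }
  rgb_image(round_half_away(pmin(pmax(arr, 0), 255)))
}

#' Serialize fixture truth as JSON
#'
#' Pixel-level matrices (gray targets, masks) are summarized rather than
#' dumped: the JSON records parameters, per-cell records and digests so a
#' sidecar stays small and diffable.
#'
#' @param truth a `truth` list from a fixture generator.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  slim <- truth
  if (!is.null(slim$grid)) slim$grid <- unclass(slim$grid)
  for (fld in c("gray_target", "gray_achieved", "conc_map", "band_mask")) {
    if (!is.null(slim[[fld]])) {
      m <- slim[[fld]]
      slim[[fld]] <- list(dim = dim(m), mean = mean(m), min = min(m), max = max(m))
    }
  }
  if (!is.null(slim$cells)) {
    slim$cells <- lapply(slim$cells, function(cl) {
      cl$mask_px <- length(cl$mask)
      cl$mask <- NULL
      cl
    })
  }
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
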