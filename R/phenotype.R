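# Root-length arithmetic and mock-exudate free-amine accounting. Tracing
# itself stays manual (points arrive via CSV); only the math lives here.

#' Manually traced root polyline
#'
#' @param points n x 2 matrix or data.frame of (row, col) pixel
#'   coordinates in trace order, n >= 2.
#' @param scale physical scale in cm per pixel, > 0.
#' @return a `root_trace` object.
#' @export
root_trace <- function(points, scale) {
  points <- as.matrix(points)
  if (nrow(points) < 2L || ncol(points) != 2L || anyNA(points)) {
    stopf("a root trace needs >= 2 (row, col) points", class = "aminoblot_domain_error")
  }
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0) {
    stopf("trace scale must be > 0 cm per pixel", class = "aminoblot_domain_error")
  }
  colnames(points) <- c("row", "col")
  structure(list(points = points, scale = scale), class = "root_trace")
}

#' Length of a traced root
#'
#' Sum of Euclidean segment lengths along the polyline, times the cm/pixel
#' scale — the segmented-line measurement.
#'
#' @param trace a [root_trace()].
#' @return length in cm.
#' @export
polyline_length <- function(trace) {
  p <- trace$points
  seg <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  sum(seg) * trace$scale
}

#' Day-indexed root length series
#'
#' @param day integer days post-germination, strictly increasing.
#' @param length_cm root lengths in cm, >= 0.
#' @return a data.frame of class `length_series`.
#' @export
length_series <- function(day, length_cm) {
  if (length(day) != length(length_cm)) {
    stopf("day and length_cm must have equal length", class = "aminoblot_domain_error")
  }
  if (any(diff(day) <= 0)) {
    stopf("days must be strictly increasing", class = "aminoblot_domain_error")
  }
  if (any(length_cm < 0)) {
    stopf("lengths must be >= 0", class = "aminoblot_domain_error")
  }
  structure(data.frame(day = as.integer(day), length_cm = length_cm),
            class = c("length_series", "data.frame"))
}

#' Growth rate from a length series
#'
#' For each day `D` with a measurement two days later, the centered
#' two-day rate `R_D = (L_{D+2} - L_D) / 2` in cm/day — blotting happens
#' every other day, so lengths arrive on a two-day grid. Days without a
#' `D + 2` partner are omitted; a sparse series yields sparse rates.
#'
#' @param series a [length_series()] (or data.frame with `day`,
#'   `length_cm`).
#' @return data.frame with columns `day` and `rate_cm_per_day`.
#' @export
growth_rate <- function(series) {
  series <- as.data.frame(series)
  d <- series$day
  l <- series$length_cm
  partner <- match(d + 2L, d)
  have <- !is.na(partner)
  data.frame(day = d[have],
             rate_cm_per_day = (l[partner[have]] - l[have]) / 2)
}

#' Mock-exudate recipe
#'
#' A defined mixture emulating root exudate composition. Free-amine group
#' counts per molecule are data, not hard-coded chemistry, so the same
#' arithmetic serves any recipe.
#'
#' @param name component names.
#' @param concentration_mM component concentrations, > 0.
#' @param free_amine_groups free -NH2 groups per molecule, integer >= 0.
#' @return a data.frame of class `mock_recipe`.
#' @export
mock_recipe <- function(name = character(), concentration_mM = numeric(),
                        free_amine_groups = integer()) {
  if (length(name) != length(concentration_mM) ||
      length(name) != length(free_amine_groups)) {
    stopf("recipe columns must have equal length", class = "aminoblot_domain_error")
  }
  if (length(concentration_mM) && any(concentration_mM <= 0)) {
    stopf("recipe concentrations must be > 0", class = "aminoblot_domain_error")
  }
  if (length(free_amine_groups) &&
      (any(free_amine_groups < 0) || any(free_amine_groups != round(free_amine_groups)))) {
    stopf("free_amine_groups must be non-negative integers",
          class = "aminoblot_domain_error")
  }
  structure(data.frame(name = as.character(name),
                       concentration_mM = as.numeric(concentration_mM),
                       free_amine_groups = as.integer(free_amine_groups),
                       stringsAsFactors = FALSE),
            class = c("mock_recipe", "data.frame"))
}

#' The 70X mock-exudate recipe
#'
#' The concentrated calibration standard: sugars and organic acids carry no
#' free amine; alanine, serine and glutamic acid carry one each, which is
#' what the ninhydrin chemistry sees. Total free amine: 23.9 mM.
#'
#' @return a [mock_recipe()].
#' @export
mock_exudate_70x <- function() {
  mock_recipe(
    name = c("glucose", "fructose", "sucrose", "citric acid", "lactic acid",
             "succinic acid", "alanine", "serine", "glutamic acid"),
    concentration_mM = c(18.4, 18.4, 9.2, 9.2, 18.4, 13.8, 9.2, 9.2, 5.5),
    free_amine_groups = c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L)
  )
}

#' Total free-amine concentration of a recipe
#'
#' Sum over components of concentration times free-amine groups per
#' molecule. Additive over recipe concatenation and homogeneous of degree 1
#' under dilution.
#'
#' @param recipe a [mock_recipe()].
#' @return total free amine, mM.
#' @export
total_free_amine <- function(recipe) {
  sum(recipe$concentration_mM * recipe$free_amine_groups)
}

#' Dilute a recipe
#'
#' Divides every concentration by `factor`; amine-group counts are
#' per-molecule properties and unchanged.
#'
#' @param recipe a [mock_recipe()].
#' @param factor dilution factor, > 0 (70 takes the 70X stock to 1X).
#' @return the diluted [mock_recipe()].
#' @export
dilute <- function(recipe, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || is.na(factor) || factor <= 0) {
    stopf("dilution factor must be > 0", class = "aminoblot_domain_error")
  }
  recipe$concentration_mM <- recipe$concentration_mM / factor
  recipe
}

#' Read a root trace from CSV
#'
#' Expected columns: `point_index`, `row`, `col` (0-based pixel
#' coordinates), ordered by `point_index`.
#'
#' @param path CSV file path.
#' @param scale cm per pixel.
#' @return a [root_trace()].
#' @export
read_trace_csv <- function(path, scale) {
  df <- utils::read.csv(path)
  need <- c("point_index", "row", "col")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stopf("trace CSV is missing column(s): %s", paste(missing, collapse = ", "),
          class = "aminoblot_data_error")
  }
  df <- df[order(df$point_index), ]
  root_trace(as.matrix(df[, c("row", "col")]), scale)
}
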