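#' Quartiles by linear interpolation of order statistics
#'
#' Q1 and Q3 computed the common spreadsheet/statistical way (R's quantile
#' type 7): with sorted values `x[1..n]`, the p-quantile sits at position
#' `h = (n-1)p + 1` and is linearly interpolated between the bracketing
#' order statistics. `method = "hinges"` gives Tukey's hinges instead;
#' hinge choice moves fence placement slightly, so the method is explicit.
#'
#' @param values numeric vector, length >= 2.
#' @param method `"linear"` (default) or `"hinges"`.
#' @return named list with `q1`, `q3`, `iqr`.
#' @examples
#' quartiles(c(1, 2, 3, 4)) # q1 = 1.75, q3 = 3.25, iqr = 1.5
#' @export
quartiles <- function(values, method = c("linear", "hinges")) {
  method <- match.arg(method)
  if (!is.numeric(values) || length(values) < 2L || anyNA(values)) {
    stopf("quartiles needs >= 2 non-missing numeric values",
          class = "aminoblot_domain_error")
  }
  if (method == "linear") {
    s <- sort.int(values, method = "quick")
    n <- length(s)
    h1 <- (n - 1) * 0.25 + 1
    f1 <- h1 %/% 1
    q1 <- s[f1] + (h1 - f1) * (s[min(f1 + 1, n)] - s[f1])
    h3 <- (n - 1) * 0.75 + 1
    f3 <- h3 %/% 1
    q3 <- s[f3] + (h3 - f3) * (s[min(f3 + 1, n)] - s[f3])
  } else {
    fn <- stats::fivenum(values)
    q1 <- fn[2]
    q3 <- fn[4]
  }
  list(q1 = q1, q3 = q3, iqr = q3 - q1)
}

#' Tukey-fence parameters
#'
#' The outlier rule flags values outside `[Q1 - k*IQR, Q3 + k*IQR]`. The
#' default `k = 0.5` is deliberately tight — the screening is meant to be
#' aggressive, discarding sensor papers whose calibration spots developed
#' atypically. A paper is discarded when at least `min_outlier_spots` of its
#' replicate spots at a single standard concentration are flagged.
#'
#' @param k fence multiplier, > 0 (default 0.5).
#' @param min_outlier_spots flagged spots at one concentration needed to
#'   discard a paper, >= 1 (default 2).
#' @param method quartile method passed to [quartiles()].
#' @return a `fence_params` object.
#' @export
fence_params <- function(k = 0.5, min_outlier_spots = 2L,
                         method = c("linear", "hinges")) {
  method <- match.arg(method)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0) {
    stopf("fence multiplier k must be > 0", class = "aminoblot_domain_error")
  }
  if (min_outlier_spots < 1L) {
    stopf("min_outlier_spots must be >= 1", class = "aminoblot_domain_error")
  }
  structure(list(k = k, min_outlier_spots = as.integer(min_outlier_spots),
                 method = method),
            class = "fence_params")
}

#' Flag values outside Tukey fences
#'
#' @param values numeric vector (>= 2 values; >= 4 recommended for the
#'   quartiles to be meaningful).
#' @param fence a [fence_params()] object.
#' @return logical vector, `TRUE` where `values[i] < Q1 - k*IQR` or
#'   `values[i] > Q3 + k*IQR`.
#' @export
fence_outliers <- function(values, fence = fence_params()) {
  q <- quartiles(values, method = fence$method)
  values < q$q1 - fence$k * q$iqr | values > q$q3 + fence$k * q$iqr
}

# Accept concentration_mM as an alias for concentration, validate presence
# of required columns.
normalize_spots <- function(spots, need_paper = FALSE) {
  spots <- as.data.frame(spots)
  if (!"concentration" %in% names(spots) && "concentration_mM" %in% names(spots)) {
    spots$concentration <- spots$concentration_mM
  }
  need <- c("concentration", "mean_intensity", if (need_paper) "paper_id")
  missing <- setdiff(need, names(spots))
  if (length(missing)) {
    stopf("spot table is missing column(s): %s", paste(missing, collapse = ", "),
          class = "aminoblot_data_error")
  }
  spots
}

#' Identify outlier sensor papers from their calibration spots
#'
#' For each standard concentration, spots from all papers in the batch are
#' pooled and Tukey fences computed; a paper is removed when at least
#' `fence$min_outlier_spots` of its spots at any single concentration fall
#' outside the fences. The rule is a per-paper quality screen: replicate
#' spots on a properly developed paper should sit inside the pooled spread.
#'
#' @param spots data.frame with columns `paper_id`, `concentration` (or
#'   `concentration_mM`) and `mean_intensity`; every paper must contribute
#'   spots at every concentration present in the batch.
#' @param fence a [fence_params()] object.
#' @return list with `retained` and `removed` (character vectors of paper
#'   ids partitioning the batch), `flags` (the input table plus an `outlier`
#'   logical column), and `reasons` (one row per removed paper and
#'   triggering concentration, with the flagged-spot count).
#' @export
flag_outlier_papers <- function(spots, fence = fence_params()) {
  spots <- normalize_spots(spots, need_paper = TRUE)
  papers <- unique(as.character(spots$paper_id))
  concs <- sort(unique(spots$concentration))
  for (p in papers) {
    have <- unique(spots$concentration[spots$paper_id == p])
    lack <- setdiff(concs, have)
    if (length(lack)) {
      stopf("paper %s has no spots at concentration %s", p,
            paste(lack, collapse = ", "), class = "aminoblot_data_error")
    }
  }
  spots$outlier <- FALSE
  for (cc in concs) {
    idx <- which(spots$concentration == cc)
    spots$outlier[idx] <- fence_outliers(spots$mean_intensity[idx], fence)
  }
  counts <- stats::aggregate(outlier ~ paper_id + concentration, data = spots, FUN = sum)
  bad <- counts[counts$outlier >= fence$min_outlier_spots, , drop = FALSE]
  removed <- unique(as.character(bad$paper_id))
  reasons <- data.frame(paper_id = as.character(bad$paper_id),
                        concentration = bad$concentration,
                        n_flagged = as.integer(bad$outlier),
                        stringsAsFactors = FALSE)
  reasons <- reasons[order(reasons$paper_id, reasons$concentration), , drop = FALSE]
  rownames(reasons) <- NULL
  list(retained = setdiff(papers, removed),
       removed = removed[order(match(removed, papers))],
       flags = spots,
       reasons = reasons)
}

#' Fit the linear intensity-vs-concentration calibration
#'
#' Ordinary least squares of spot mean intensity (y) on free-amine
#' concentration (x): `intensity = slope * concentration + intercept`.
#' The developed color darkens with analyte, so the slope is negative on
#' real papers (reference line: intensity = -20.98 x + 241.71). The fitted
#' object carries everything inverse prediction and confidence intervals
#' need: residual standard error, `x_mean` and `sxx`.
#'
#' @param spots data.frame with columns `concentration` (or
#'   `concentration_mM`) and `mean_intensity`; >= 3 spots at >= 2 distinct
#'   concentrations.
#' @param level confidence level stored with the model (default 0.95).
#' @param clamp_max ceiling for inverse-predicted concentrations; defaults
#'   to the highest concentration in `spots`.
#' @return a `calibration_model` object with elements `slope`, `intercept`,
#'   `r_squared`, `p_value` (two-sided test of zero slope), `n`,
#'   `residual_se`, `x_mean`, `sxx`, `level`, `clamp_max`.
#' @export
fit_calibration <- function(spots, level = 0.95, clamp_max = NULL) {
  spots <- normalize_spots(spots)
  x <- spots$concentration
  y <- spots$mean_intensity
  if (length(x) < 3L) {
    stopf("calibration needs >= 3 spots (got %d)", length(x),
          class = "aminoblot_domain_error")
  }
  if (length(unique(x)) < 2L) {
    stopf("degenerate design: all calibration concentrations are identical",
          class = "aminoblot_domain_error")
  }
  fit <- stats::lm(y ~ x)
  # noise-free calibrations legitimately fit perfectly; keep that quiet
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = unname(sm$coefficients[2, 4]),
    n = length(x),
    residual_se = sm$sigma,
    x_mean = mean(x),
    sxx = sum((x - mean(x))^2),
    level = level,
    clamp_max = clamp_max %||% max(x)
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Calibration: intensity = %.4f * conc + %.4f\n", x$slope, x$intercept))
  cat(sprintf("  n = %d spots, R^2 = %.4f, p(slope) = %.3g\n", x$n, x$r_squared, x$p_value))
  cat(sprintf("  residual SE = %.4f, %d%% CI level, clamp at %.2f mM\n",
              x$residual_se, round(100 * x$level), x$clamp_max))
  invisible(x)
}

#' Confidence band for the calibration line
#'
#' Interval for the mean response at concentration `x`:
#' `yhat +- t(level, n-2) * s * sqrt(1/n + (x - x_mean)^2 / sxx)`.
#' This is the band for the regression line itself (narrowest at `x_mean`),
#' not a prediction interval for a new spot; set
#' `interval = "prediction"` for the latter (adds 1 under the square root).
#'
#' @param model a `calibration_model`.
#' @param x concentration(s), mM.
#' @param level optional override of the model's confidence level.
#' @param interval `"confidence"` (default) or `"prediction"`.
#' @return data.frame with columns `x`, `fit`, `lower`, `upper`.
#' @export
ci_mean_response <- function(model, x, level = NULL,
                             interval = c("confidence", "prediction")) {
  interval <- match.arg(interval)
  level <- level %||% model$level
  if (model$n <= 2L) {
    stopf("confidence interval needs n > 2 (got n = %d)", model$n,
          class = "aminoblot_domain_error")
  }
  fit <- model$slope * x + model$intercept
  extra <- if (interval == "prediction") 1 else 0
  se <- model$residual_se * sqrt(extra + 1 / model$n + (x - model$x_mean)^2 / model$sxx)
  tq <- stats::qt(1 - (1 - level) / 2, df = model$n - 2L)
  data.frame(x = x, fit = fit, lower = fit - tq * se, upper = fit + tq * se)
}

#' Inverse prediction: intensity to concentration
#'
#' Inverts the calibration line, `conc = (intensity - intercept) / slope`,
#' then clamps to `[0, clamp_max]`: pixels brighter than the intercept would
#' predict negative concentrations (no analyte), and pixels darker than the
#' line's value at the top standard are reported at the ceiling rather than
#' extrapolated beyond the calibrated range.
#'
#' @param model a `calibration_model` with nonzero slope.
#' @param intensity numeric vector or matrix of intensities.
#' @param clamp clamp to `[0, clamp_max]`? Default `TRUE`.
#' @param clamp_max override of the model's ceiling.
#' @return concentrations in mM, same shape as `intensity`.
#' @export
intensity_to_conc <- function(model, intensity, clamp = TRUE, clamp_max = NULL) {
  if (model$slope == 0) {
    stopf("degenerate model: zero slope cannot be inverted",
          class = "aminoblot_domain_error")
  }
  conc <- (intensity - model$intercept) / model$slope
  if (clamp) {
    conc <- pmin(pmax(conc, 0), clamp_max %||% model$clamp_max)
  }
  conc
}

#' Concentration resolution implied by the confidence band
#'
#' At each standard, the width of the confidence band in intensity units is
#' converted to a concentration range by dividing by `|slope|`; the mean
#' across standards summarizes the quantification resolution of the batch.
#'
#' @param model a `calibration_model`.
#' @param standards concentrations, mM (non-empty).
#' @param level,interval passed to [ci_mean_response()].
#' @return list with `per_standard` (named mM ranges) and `mean_range`.
#' @export
estimate_resolution <- function(model, standards, level = NULL,
                                interval = c("confidence", "prediction")) {
  if (length(standards) == 0L) {
    stopf("standards must be non-empty", class = "aminoblot_domain_error")
  }
  ci <- ci_mean_response(model, standards, level = level,
                         interval = match.arg(interval))
  rng <- (ci$upper - ci$lower) / abs(model$slope)
  names(rng) <- format(standards)
  list(per_standard = rng, mean_range = mean(rng))
}

#' Serialize / restore a calibration model as JSON
#'
#' @param model a `calibration_model`; may carry optional `retained` /
#'   `removed` paper-id vectors added by the calibration pipeline.
#' @param path JSON file path.
#' @return `write_calibration_model` returns `path` invisibly;
#'   `read_calibration_model` returns a `calibration_model`.
#' @export
write_calibration_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_calibration_model
#' @export
read_calibration_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("slope", "intercept", "n", "residual_se", "x_mean", "sxx",
            "level", "clamp_max")
  missing <- setdiff(need, names(obj))
  if (length(missing)) {
    stopf("calibration JSON %s is missing field(s): %s", path,
          paste(missing, collapse = ", "), class = "aminoblot_data_error")
  }
  structure(obj, class = "calibration_model")
}
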