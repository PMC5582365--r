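# Significance machinery: two-factor ANOVA with Tukey HSD pairwise
# comparisons on spot intensities, and the limit-of-detection rule built on
# top of it.

# Pick the primary-factor column: concentration for sensitivity data, day
# for stability data, or a generic `level` column.
primary_column <- function(observations) {
  for (cand in c("concentration", "day", "level")) {
    if (cand %in% names(observations)) return(cand)
  }
  stopf("observations need a `concentration`, `day` or `level` column",
        class = "aminoblot_data_error")
}

#' Two-factor ANOVA with Tukey HSD pairwise comparisons
#'
#' Fixed-effects two-way ANOVA of intensity on the primary factor
#' (concentration or day) plus sensor paper, without interaction by default
#' (two named factors, additive model), followed by Tukey's honestly
#' significant difference test over all primary-factor level pairs.
#'
#' @param observations data.frame with columns `value` (intensity in
#'   \[0, 255\]), a primary-factor column (`concentration`, `day` or
#'   `level`) and `paper_id`. Every primary-level x paper cell must be
#'   non-empty.
#' @param alpha significance level for the `significant` flag
#'   (default 0.01).
#' @param interaction include the interaction term? Default `FALSE`.
#' @return list of class `anova2_tukey` with `anova` (F table),
#'   `pairwise` (data.frame `level_a`, `level_b`, `estimate`, `p_value`,
#'   `significant`, where `estimate` is mean(level_b) - mean(level_a)),
#'   `alpha`, and `primary` (the factor column used).
#' @export
anova2_tukey <- function(observations, alpha = 0.01, interaction = FALSE) {
  observations <- as.data.frame(observations)
  prim <- primary_column(observations)
  need <- c("value", "paper_id")
  missing <- setdiff(need, names(observations))
  if (length(missing)) {
    stopf("observations are missing column(s): %s", paste(missing, collapse = ", "),
          class = "aminoblot_data_error")
  }
  if (anyNA(observations$value) || min(observations$value) < 0 ||
      max(observations$value) > 255) {
    stopf("intensity values must be in [0, 255]", class = "aminoblot_domain_error")
  }
  lev <- factor(observations[[prim]])
  pap <- factor(observations$paper_id)
  if (nlevels(lev) < 2L) {
    stopf("need >= 2 levels of the primary factor", class = "aminoblot_domain_error")
  }
  cell <- table(lev, pap)
  if (any(cell == 0L)) {
    empty <- which(cell == 0L, arr.ind = TRUE)[1, ]
    stopf("unbalanced design: empty cell (%s = %s, paper_id = %s)",
          prim, rownames(cell)[empty[1]], colnames(cell)[empty[2]],
          class = "aminoblot_data_error")
  }
  df <- data.frame(value = observations$value, lev = lev, pap = pap)
  form <- if (interaction) value ~ lev + pap + lev:pap else value ~ lev + pap
  fit <- stats::aov(form, data = df)
  tk <- stats::TukeyHSD(fit, which = "lev")$lev
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairwise <- data.frame(
    level_a = vapply(pairs, `[`, character(1), 2L),
    level_b = vapply(pairs, `[`, character(1), 1L),
    estimate = unname(tk[, "diff"]),
    p_value = unname(tk[, "p adj"]),
    stringsAsFactors = FALSE
  )
  # zero-variance data yields NaN p-values: not evidence of a difference
  pairwise$significant <- !is.na(pairwise$p_value) & pairwise$p_value < alpha
  atab <- summary(fit)[[1]]
  structure(list(anova = atab, pairwise = pairwise, alpha = alpha,
                 primary = prim),
            class = "anova2_tukey")
}

#' @export
print.anova2_tukey <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (%s + paper) with Tukey HSD, alpha = %g\n",
              x$primary, x$alpha))
  print(x$anova)
  cat(sprintf("%d pairwise comparisons, %d significant\n",
              nrow(x$pairwise), sum(x$pairwise$significant)))
  invisible(x)
}

#' Limit of detection against the water control
#'
#' The smallest concentration whose Tukey HSD comparison against the 0 mM
#' control is significant at `alpha`, provided every larger tested
#' concentration is also significant — an isolated significant level above
#' a non-significant gap does not set the limit. Returns `NA` when no
#' concentration qualifies.
#'
#' @param observations as in [anova2_tukey()], with a `concentration`
#'   column that includes a 0 mM (water) control.
#' @param alpha significance level (default 0.01).
#' @param interaction passed to [anova2_tukey()].
#' @return the detection limit in mM, or `NA_real_`.
#' @export
detection_limit <- function(observations, alpha = 0.01, interaction = FALSE) {
  observations <- as.data.frame(observations)
  if (!"concentration" %in% names(observations)) {
    stopf("detection_limit needs a `concentration` column",
          class = "aminoblot_data_error")
  }
  if (!any(observations$concentration == 0)) {
    stopf("observations must include a 0 mM control", class = "aminoblot_domain_error")
  }
  res <- anova2_tukey(observations, alpha = alpha, interaction = interaction)
  pw <- res$pairwise
  ctrl <- format(0)
  vs0 <- pw[pw$level_a == ctrl | pw$level_b == ctrl, , drop = FALSE]
  other <- ifelse(vs0$level_a == ctrl, vs0$level_b, vs0$level_a)
  conc <- as.numeric(other)
  ord <- order(conc)
  conc <- conc[ord]
  sig <- vs0$significant[ord]
  # longest all-significant run ending at the highest concentration
  if (!length(sig) || !sig[length(sig)]) return(NA_real_)
  run_start <- length(sig)
  while (run_start > 1L && sig[run_start - 1L]) run_start <- run_start - 1L
  conc[run_start]
}

#' Synthetic sensitivity batch with a known detection threshold
#'
#' Emulates a dilution-series sensitivity experiment: replicate spots of
#' mock exudate at each concentration on several papers. Spots at
#' concentrations below `threshold` develop like the water control;
#' from `threshold` upward the mean intensity follows the calibration line
#' `slope * conc + intercept`. Paper-to-paper offsets and within-paper spot
#' noise are Gaussian. The generating threshold is the fixture's
#' ground-truth detection limit.
#'
#' @param concentrations tested mM levels including the 0 control.
#' @param threshold smallest concentration with a real effect (mM).
#' @param n_papers sheets (default 4).
#' @param spots_per_paper replicate spots per concentration per sheet
#'   (default 9).
#' @param noise_sd within-paper spot noise, intensity units (default 2).
#' @param paper_sd between-paper offset SD, intensity units (default 1).
#' @param slope,intercept generating calibration line.
#' @param seed RNG seed.
#' @return data.frame with `value`, `concentration`, `paper_id`, plus a
#'   `truth` attribute recording the generating parameters.
#' @export
make_sensitivity_batch <- function(concentrations = c(0, 0.03, 0.07, 0.14,
                                                      0.35, 0.7, 1.71, 3.41),
                                   threshold = 0.14, n_papers = 4L,
                                   spots_per_paper = 9L, noise_sd = 2,
                                   paper_sd = 1, slope = -20.98,
                                   intercept = 241.71, seed = 1L) {
  if (!0 %in% concentrations) {
    stopf("concentrations must include the 0 mM control",
          class = "aminoblot_domain_error")
  }
  with_seed(seed, {
    papers <- sprintf("P%02d", seq_len(n_papers))
    offsets <- stats::rnorm(n_papers, 0, paper_sd)
    grid <- expand.grid(rep = seq_len(spots_per_paper),
                        concentration = concentrations,
                        paper = seq_len(n_papers))
    mu <- ifelse(grid$concentration >= threshold & grid$concentration > 0,
                 slope * grid$concentration + intercept, intercept)
    value <- mu + offsets[grid$paper] + stats::rnorm(nrow(grid), 0, noise_sd)
    out <- data.frame(value = pmin(pmax(value, 0), 255),
                      concentration = grid$concentration,
                      paper_id = papers[grid$paper],
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- list(threshold = threshold, slope = slope,
                               intercept = intercept, noise_sd = noise_sd,
                               paper_sd = paper_sd, seed = seed)
    out
  })
}
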