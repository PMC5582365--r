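test_that("quartiles match the linear-interpolation definition", {
  q <- quartiles(c(1, 2, 3, 4))
  expect_equal(q$q1, 1.75)
  expect_equal(q$q3, 3.25)
  expect_equal(q$iqr, 1.5)
  expect_equal(quartiles(c(5, 5, 5, 5))$iqr, 0)
  qc <- quartiles(rep(7.5, 6))
  expect_equal(qc$q1, qc$q3)
  expect_error(quartiles(3), class = "aminoblot_domain_error")
})

test_that("quartiles agree with stats::quantile type 7 on random data", {
  set.seed(31)
  for (i in 1:25) {
    v <- rnorm(sample(2:40, 1))
    q <- quartiles(v)
    expect_equal(q$q1, unname(stats::quantile(v, 0.25, type = 7)))
    expect_equal(q$q3, unname(stats::quantile(v, 0.75, type = 7)))
  }
})

test_that("fence_outliers flags exactly the values outside Q1/Q3 fences", {
  expect_equal(fence_outliers(c(10, 10, 10, 10, 100)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(fence_outliers(rep(3, 6))))
  expect_false(any(fence_outliers(c(-2, -1, 0, 1, 2)))) # symmetric, no extremes
  f <- fence_params(k = 1.5)
  expect_false(any(fence_outliers(c(1, 2, 3, 4, 5), f)))
  expect_equal(fence_outliers(c(1, 2, 3, 4, 10), f),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("fence_params validates its fields", {
  expect_error(fence_params(k = 0), class = "aminoblot_domain_error")
  expect_error(fence_params(min_outlier_spots = 0), class = "aminoblot_domain_error")
  expect_equal(fence_params()$k, 0.5)
  expect_equal(fence_params()$min_outlier_spots, 2L)
})

make_screen_batch <- function(shift_paper = NULL, shift = 60, n_shift = 3) {
  # 4 papers x 2 concentrations x 3 replicates, deterministic spread
  base <- expand.grid(rep = 1:3, paper_id = c("A", "B", "C", "D"),
                      concentration = c(1.71, 4.71))
  base$mean_intensity <- 200 - 20 * (base$concentration == 4.71) +
    c(-1, 0, 1)[base$rep] + 0.1 * as.integer(factor(base$paper_id))
  if (!is.null(shift_paper)) {
    sel <- which(base$paper_id == shift_paper & base$concentration == 4.71)
    base$mean_intensity[sel[seq_len(n_shift)]] <-
      base$mean_intensity[sel[seq_len(n_shift)]] + shift
  }
  base
}

test_that("flag_outlier_papers removes exactly the shifted paper", {
  batch <- make_screen_batch(shift_paper = "C")
  res <- flag_outlier_papers(batch)
  expect_equal(res$removed, "C")
  expect_setequal(res$retained, c("A", "B", "D"))
  # manual fence oracle at the shifted concentration
  v <- batch$mean_intensity[batch$concentration == 4.71]
  q <- quartiles(v)
  manual <- v < q$q1 - 0.5 * q$iqr | v > q$q3 + 0.5 * q$iqr
  expect_equal(res$flags$outlier[res$flags$concentration == 4.71], manual)
  expect_equal(res$reasons$paper_id, "C")
  expect_equal(res$reasons$concentration, 4.71)
})

test_that("identical papers are all retained; single flags do not remove", {
  flat <- make_screen_batch()
  flat$mean_intensity <- 200 - 20 * (flat$concentration == 4.71)
  res <- flag_outlier_papers(flat)
  expect_length(res$removed, 0)
  expect_setequal(res$retained, c("A", "B", "C", "D"))

  # one extreme spot per concentration: flagged, but never >= 2 at one conc
  single <- make_screen_batch(shift_paper = "B", shift = 80, n_shift = 1)
  res1 <- flag_outlier_papers(single)
  expect_true(any(res1$flags$outlier))
  expect_false("B" %in% res1$removed)
})

test_that("flag_outlier_papers is invariant to paper order and validates structure", {
  batch <- make_screen_batch(shift_paper = "A")
  perm <- batch[sample(nrow(batch)), ]
  expect_setequal(flag_outlier_papers(perm)$removed,
                  flag_outlier_papers(batch)$removed)

  broken <- batch[!(batch$paper_id == "D" & batch$concentration == 1.71), ]
  expect_error(flag_outlier_papers(broken), "D", class = "aminoblot_data_error")
})

test_that("fit_calibration reproduces the reference line on noise-free spots", {
  batch <- make_calibration_batch(n_papers = 1, noise_sd = 0, seed = 1)
  m <- fit_calibration(batch$spots)
  expect_lt(abs(m$slope - (-20.98)), 1e-9)
  expect_lt(abs(m$intercept - 241.71), 1e-9)
  expect_equal(m$r_squared, 1.0, tolerance = 1e-12)
  expect_equal(m$n, 9L)
  expect_equal(m$clamp_max, 4.71)
})

test_that("fit_calibration matches the closed-form OLS oracle on noisy data", {
  set.seed(77)
  x <- rep(c(1.71, 3.41, 4.71), each = 10)
  y <- -20.98 * x + 241.71 + rnorm(30, 0, 5)
  m <- fit_calibration(data.frame(concentration = x, mean_intensity = y))
  # normal-equation oracle
  sxx <- sum((x - mean(x))^2)
  slope_o <- sum((x - mean(x)) * (y - mean(y))) / sxx
  int_o <- mean(y) - slope_o * mean(x)
  resid <- y - (int_o + slope_o * x)
  se_o <- sqrt(sum(resid^2) / (30 - 2))
  r2_o <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  t_o <- slope_o / (se_o / sqrt(sxx))
  p_o <- 2 * pt(-abs(t_o), df = 28)
  expect_lt(abs(m$slope - slope_o), 1e-9)
  expect_lt(abs(m$intercept - int_o), 1e-9)
  expect_lt(abs(m$residual_se - se_o), 1e-9)
  expect_lt(abs(m$r_squared - r2_o), 1e-9)
  expect_lt(abs(m$p_value - p_o), 1e-12)
  expect_equal(m$x_mean, mean(x))
  expect_equal(m$sxx, sxx)
})

test_that("fit_calibration rejects degenerate designs", {
  expect_error(fit_calibration(data.frame(concentration = c(1, 1, 1),
                                          mean_intensity = c(1, 2, 3))),
               class = "aminoblot_domain_error")
  expect_error(fit_calibration(data.frame(concentration = c(1, 2),
                                          mean_intensity = c(1, 2))),
               class = "aminoblot_domain_error")
  # minimal collinear fit
  m <- fit_calibration(data.frame(concentration = c(0, 1, 2),
                                  mean_intensity = c(0, 1, 2)))
  expect_equal(m$slope, 1)
  expect_equal(m$intercept, 0, tolerance = 1e-12)
})

test_that("ci_mean_response matches predict.lm and leverage is minimal at x_mean", {
  set.seed(12)
  x <- rep(c(1.71, 3.41, 4.71), each = 8)
  y <- -20.98 * x + 241.71 + rnorm(24, 0, 4)
  m <- fit_calibration(data.frame(concentration = x, mean_intensity = y))
  xs <- c(0.5, 1.71, m$x_mean, 4.71, 6)
  ci <- ci_mean_response(m, xs)
  oracle <- predict(lm(y ~ x), newdata = data.frame(x = xs),
                    interval = "confidence", level = 0.95)
  expect_lt(max(abs(ci$fit - oracle[, "fit"])), 1e-9)
  expect_lt(max(abs(ci$lower - oracle[, "lwr"])), 1e-9)
  expect_lt(max(abs(ci$upper - oracle[, "upr"])), 1e-9)
  widths <- ci$upper - ci$lower
  expect_true(all(widths >= widths[xs == m$x_mean] - 1e-12))
  # prediction interval is strictly wider
  pi <- ci_mean_response(m, xs, interval = "prediction")
  expect_true(all(pi$upper - pi$lower > widths))
})

test_that("ci_mean_response is zero-width on noise-free fits", {
  m <- fit_calibration(make_calibration_batch(n_papers = 1, noise_sd = 0)$spots)
  ci <- ci_mean_response(m, c(1.71, 3.41, 4.71))
  expect_lt(max(ci$upper - ci$lower), 1e-9)
})

test_that("intensity_to_conc inverts and clamps the calibration line", {
  m <- fit_calibration(make_calibration_batch(n_papers = 1, noise_sd = 0)$spots)
  expect_equal(intensity_to_conc(m, m$intercept), 0)
  cs <- seq(0, 4.71, by = 0.37)
  expect_lt(max(abs(intensity_to_conc(m, m$slope * cs + m$intercept) - cs)), 1e-9)
  expect_equal(intensity_to_conc(m, m$intercept + 25), 0)     # brighter than blank
  expect_equal(intensity_to_conc(m, 0), 4.71)                 # darker than top standard
  expect_equal(intensity_to_conc(m, 0, clamp = FALSE),
               (0 - m$intercept) / m$slope)
  m0 <- m
  m0$slope <- 0
  expect_error(intensity_to_conc(m0, 100), class = "aminoblot_domain_error")
})

test_that("estimate_resolution converts CI widths by dividing by |slope|", {
  set.seed(4)
  x <- rep(c(1.71, 3.41, 4.71), each = 12)
  y <- -20.98 * x + 241.71 + rnorm(36, 0, 6)
  m <- fit_calibration(data.frame(concentration = x, mean_intensity = y))
  stds <- c(1.71, 3.41, 4.71)
  res <- estimate_resolution(m, stds)
  ci <- ci_mean_response(m, stds)
  expect_equal(unname(res$per_standard), (ci$upper - ci$lower) / abs(m$slope))
  expect_equal(res$mean_range, mean(res$per_standard))
  # an intensity range of 19 units under the reference slope is ~0.906 mM
  expect_equal(19 / abs(-20.98), 0.9056, tolerance = 1e-3)
  m0 <- fit_calibration(make_calibration_batch(n_papers = 1, noise_sd = 0)$spots)
  expect_lt(max(estimate_resolution(m0, stds)$per_standard), 1e-9)
  expect_error(estimate_resolution(m, numeric(0)), class = "aminoblot_domain_error")
})

test_that("calibration models serialize to JSON and back", {
  m <- fit_calibration(make_calibration_batch(n_papers = 2, noise_sd = 2,
                                              seed = 5)$spots)
  m$retained <- c("P01", "P02")
  m$removed <- character(0)
  p <- withr::local_tempfile(fileext = ".json")
  write_calibration_model(m, p)
  back <- read_calibration_model(p)
  for (fld in c("slope", "intercept", "r_squared", "p_value", "residual_se",
                "x_mean", "sxx", "level", "clamp_max")) {
    expect_equal(back[[fld]], m[[fld]], tolerance = 1e-12)
  }
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(slope = 1), bad, auto_unbox = TRUE)
  expect_error(read_calibration_model(bad), class = "aminoblot_data_error")
})
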