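test_that("make_calibration_batch is a pure function of parameters and seed", {
  a <- make_calibration_batch(seed = 7)
  b <- make_calibration_batch(seed = 7)
  c <- make_calibration_batch(seed = 8)
  expect_identical(a$spots, b$spots)
  expect_false(identical(a$spots$mean_intensity, c$spots$mean_intensity))
})

test_that("noise-free batches reproduce the generating line exactly", {
  batch <- make_calibration_batch(n_papers = 3, noise_sd = 0, seed = 2)
  m <- fit_calibration(batch$spots)
  expect_lt(abs(m$slope - batch$truth$slope), 1e-9)
  expect_lt(abs(m$intercept - batch$truth$intercept), 1e-9)
})

test_that("designated outlier papers are recovered by the fence screen", {
  batch <- make_calibration_batch(n_papers = 10, noise_sd = 3,
                                  outlier_papers = c("P03", "P07"), seed = 5)
  res <- flag_outlier_papers(batch$spots)
  expect_true(all(c("P03", "P07") %in% res$removed)) # 100% recall
  # the shifted spots themselves are flagged
  shifted <- batch$spots$paper_id %in% c("P03", "P07") &
    batch$spots$concentration_mM == 3.41
  expect_true(all(res$flags$outlier[shifted]))
})

test_that("outlier specs are validated", {
  expect_error(make_calibration_batch(outlier_papers = "P99"),
               class = "aminoblot_spec_error")
  expect_error(make_calibration_batch(
    outlier_papers = list(list(paper_id = "P01", concentration = 9.9))),
    class = "aminoblot_spec_error")
  expect_error(make_calibration_batch(n_papers = 0), class = "aminoblot_domain_error")
})

test_that("blot images encode the gray contract exactly through the purple tint", {
  fx <- make_blot_image(noise_sd = 0, seed = 4)
  g <- to_gray(fx$image)
  # weighted intensity equals the 2-decimal-quantized gray target
  expect_lt(max(abs(unclass(g) - fx$truth$gray_target)), 0.005 + 1e-9)
  expect_equal(unclass(g), fx$truth$gray_achieved, ignore_attr = TRUE)
})

test_that("blot fixtures are deterministic and concentration truth round-trips", {
  f1 <- make_blot_image(noise_sd = 0.8, seed = 10)
  f2 <- make_blot_image(noise_sd = 0.8, seed = 10)
  expect_identical(unclass(f1$image), unclass(f2$image))
  f3 <- make_blot_image(noise_sd = 0.8, seed = 11)
  expect_false(identical(unclass(f1$image), unclass(f3$image)))

  m <- fit_calibration(make_calibration_batch(n_papers = 1, noise_sd = 0)$spots)
  cm <- concentration_map(to_gray(f1$image), m)
  expect_lt(max(abs(cm$conc - f1$truth$conc_map)), 1e-9)
})

test_that("zero-concentration trace bands are indistinguishable from background", {
  trace <- cbind(c(20, 150, 285), c(180, 170, 190))
  fx <- make_blot_image(trace = trace, profile = 0, noise_sd = 0, seed = 1)
  expect_equal(max(fx$truth$gray_target), fx$truth$background)
  expect_equal(min(fx$truth$gray_target[fx$truth$band_mask]), fx$truth$background)
})

test_that("geometry violations raise layout errors", {
  # trace through the calibration grid
  expect_error(make_blot_image(trace = cbind(c(10, 100), c(10, 100)),
                               profile = 2, seed = 1),
               class = "aminoblot_layout_error")
  # grid that does not fit
  expect_error(make_blot_image(width = 60, height = 60, seed = 1),
               class = "aminoblot_layout_error")
  expect_error(make_root_scan(cbind(c(0, 500), c(0, 10))),
               class = "aminoblot_layout_error")
})

test_that("root scans are deterministic and handle 2-point traces", {
  trace <- cbind(c(10, 280), c(100, 120))
  a <- make_root_scan(trace, seed = 3)
  b <- make_root_scan(trace, seed = 3)
  expect_identical(unclass(a), unclass(b))
  expect_equal(dim(a), c(300, 220, 3))
})

test_that("paired fixtures align under overlay with a recorded offset", {
  trace_root <- cbind(c(40, 120, 200), c(150, 170, 160))
  off <- c(12, -5)
  trace_blot <- sweep(trace_root, 2, off) # blot drew the trace shifted by -off
  blot <- make_blot_image(width = 220, height = 300, trace = trace_blot,
                          profile = 4.5, noise_sd = 0, seed = 6)
  root <- make_root_scan(trace_root, width = 220, height = 300)
  ov <- overlay(root, blot$image, offset = off)
  # at a trace vertex the blot band darkens the pale root band
  plain <- overlay(root, rgb_image(array(255, dim = c(300, 220, 3))))
  v <- trace_root[2, ] + 1
  expect_lt(mean(ov[v[1], v[2], ]), 0.75 * mean(plain[v[1], v[2], ]))
})

test_that("end-to-end recovery is unbiased within the stated noise bound", {
  # scaled down from 200 to 120 seeds to stay inside the suite budget
  noise_sd <- 2
  grid <- grid_spec(3, 3, pitch = 30, origin = c(20, 20), expected_radius = 8)
  errs <- matrix(NA_real_, 120, 9)
  area <- NA
  for (s in 1:120) {
    batch <- make_calibration_batch(n_papers = 4, noise_sd = 2, seed = 4000 + s)
    model <- fit_calibration(batch$spots)
    blot <- make_blot_image(width = 100, height = 100, grid = grid,
                            noise_sd = noise_sd, seed = 5000 + s)
    g <- to_gray(blot$image)
    for (i in seq_len(9)) {
      cell <- blot$truth$cells[[i]]
      area <- length(cell$mask)
      meas <- mean(unclass(g)[cell$mask])
      errs[s, i] <- intensity_to_conc(model, meas) - cell$concentration
    }
  }
  bound <- 2 * noise_sd / abs(-20.98) * sqrt(1 / area)
  expect_lt(max(abs(colMeans(errs))), bound)
})

test_that("truth JSON summarizes fixtures without binary payloads", {
  fx <- make_blot_image(noise_sd = 0, seed = 1)
  p <- withr::local_tempfile(fileext = ".json")
  write_truth_json(fx$truth, p)
  truth <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(truth$slope, -20.98)
  expect_equal(truth$cells$concentration, rep(c(1.71, 3.41, 4.71), each = 3))
  expect_true(all(truth$cells$mask_px > 0))
  expect_lt(file.size(p), 64e3)
})
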