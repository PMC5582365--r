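test_that("flood_select covers a uniform image and isolates unique seeds", {
  uni <- gray_image(matrix(120, 9, 7))
  s <- flood_select(uni, seed = c(4, 3), tolerance = 0)
  expect_equal(s$area, 9 * 7)
  expect_true(s$touches_border)

  m <- matrix(100, 9, 7)
  m[5, 4] <- 180 # unique value at the seed
  s1 <- flood_select(gray_image(m), seed = c(4, 3), tolerance = 0)
  expect_equal(s1$area, 1)
  expect_equal(unname(s1$centroid), c(4, 3))
  expect_false(s1$touches_border)
})

test_that("flood_select recovers exactly the drawn disk", {
  fx <- draw_disks(40, 40, background = 220, centers = rbind(c(19, 19)),
                   radius = 7, intensity = 120)
  s <- flood_select(fx$image, seed = c(19, 19), tolerance = 20)
  truth <- which(fx$masks[[1]], arr.ind = TRUE) - 1L
  got <- s$pixels[order(s$pixels[, 1], s$pixels[, 2]), ]
  want <- truth[order(truth[, 1], truth[, 2]), ]
  expect_equal(unname(got), unname(want))
  expect_equal(s$mean_intensity, 120)
})

test_that("flood_select errors on out-of-bounds seeds and bad tolerance", {
  uni <- gray_image(matrix(0, 5, 5))
  expect_error(flood_select(uni, seed = c(5, 0)), class = "aminoblot_coordinate_error")
  expect_error(flood_select(uni, seed = c(-1, 2)), class = "aminoblot_coordinate_error")
  expect_error(flood_select(uni, seed = c(1, 1), tolerance = -1),
               class = "aminoblot_domain_error")
  expect_error(flood_select(uni, seed = c(1, 1), connectivity = 6),
               class = "aminoblot_domain_error")
})

test_that("flood_select is idempotent across member seeds when variation <= tol/2", {
  set.seed(9)
  fx <- draw_disks(30, 30, background = 230, centers = rbind(c(14, 14)),
                   radius = 6, intensity = 130)
  m <- unclass(fx$image)
  jitter <- matrix(runif(900, -5, 5), 30, 30) # tol/2 = 10, variation <= 10
  m[fx$masks[[1]]] <- m[fx$masks[[1]]] + jitter[fx$masks[[1]]]
  img <- gray_image(m)
  ref <- flood_select(img, seed = c(14, 14), tolerance = 20)
  for (i in sample(nrow(ref$pixels), 5)) {
    again <- flood_select(img, seed = ref$pixels[i, ], tolerance = 20)
    expect_equal(sort(again$pixels[, 1] * 30 + again$pixels[, 2]),
                 sort(ref$pixels[, 1] * 30 + ref$pixels[, 2]))
  }
})

test_that("spot_mean_intensity averages member pixels", {
  img <- gray_image(matrix(c(42, 0, 255, 10), 2, 2))
  expect_equal(spot_mean_intensity(manual_spot(cbind(0, 0)), img), 42)
  expect_equal(spot_mean_intensity(manual_spot(rbind(c(1, 0), c(0, 1))), img),
               127.5)
  # random 10-pixel spot vs explicit sum/length oracle
  set.seed(5)
  big <- gray_image(matrix(runif(400, 0, 255), 20, 20))
  px <- cbind(sample(0:19, 10, TRUE), sample(0:19, 10, TRUE))
  px <- unique(px)
  vals <- unclass(big)[px + 1L]
  expect_equal(spot_mean_intensity(manual_spot(px), big), sum(vals) / nrow(px))
  expect_error(spot_mean_intensity(manual_spot(px[0, , drop = FALSE]), big),
               class = "aminoblot_domain_error")
  expect_error(spot_mean_intensity(manual_spot(cbind(25, 2)), big),
               class = "aminoblot_coordinate_error")
})

test_that("detect_grid finds a perfect synthetic grid within tolerance", {
  fx <- make_blot_image(noise_sd = 0, seed = 2)
  gray <- to_gray(fx$image)
  spots <- detect_grid(gray, test_grid())
  expect_length(spots, 9)
  for (i in seq_along(spots)) {
    truth <- fx$truth$cells[[i]]
    expect_lt(max(abs(spots[[i]]$centroid - c(truth$row, truth$col))), 1)
    expect_lt(abs(spots[[i]]$mean_intensity - truth$target_intensity), 0.5)
  }
})

test_that("detect_grid fails informatively on blank or incomplete grids", {
  blank <- gray_image(matrix(240, 150, 150))
  expect_error(detect_grid(blank, test_grid()),
               class = "aminoblot_detection_error")

  # 3 x 3 grid with the center disk (r2c2) missing
  centers <- as.matrix(expand.grid(row = c(24, 58, 92), col = c(24, 58, 92)))
  centers <- centers[!(centers[, 1] == 58 & centers[, 2] == 58), ]
  fx <- draw_disks(150, 150, background = 240, centers = centers,
                   radius = 10, intensity = 150)
  expect_error(detect_grid(fx$image, test_grid()), "r2c2",
               class = "aminoblot_detection_error")
})

test_that("spot_table follows the CSV schema and row-major standard order", {
  fx <- make_blot_image(noise_sd = 0, seed = 2)
  spots <- detect_grid(to_gray(fx$image), test_grid())
  tab <- spot_table(spots, test_grid(), paper_id = "P01",
                    standards = c(1.71, 3.41, 4.71))
  expect_named(tab, c("paper_id", "grid_cell", "concentration_mM",
                      "mean_intensity", "area_px", "centroid_row",
                      "centroid_col", "touches_border"))
  expect_equal(tab$grid_cell[1:4], c("r1c1", "r1c2", "r1c3", "r2c1"))
  expect_equal(tab$concentration_mM, rep(c(1.71, 3.41, 4.71), each = 3))
})

test_that("grid_spec validates its geometry", {
  expect_error(grid_spec(3, 3, pitch = 18, origin = c(0, 0), expected_radius = 10),
               class = "aminoblot_domain_error")
  expect_error(grid_spec(0, 3, pitch = 40, origin = c(0, 0), expected_radius = 10),
               class = "aminoblot_domain_error")
})
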