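# Shared fixture builders. Everything is generated in code; nothing binary
# ships with the package.

# Gray image: uniform background with filled disks at given centers
# (0-based), radii and intensities.
draw_disks <- function(h, w, background, centers, radius, intensity) {
  m <- matrix(background, h, w)
  rr <- matrix(0:(h - 1), h, w)
  cc <- matrix(0:(w - 1), h, w, byrow = TRUE)
  masks <- vector("list", nrow(centers))
  for (i in seq_len(nrow(centers))) {
    mask <- (rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radius^2
    m[mask] <- intensity[min(i, length(intensity))]
    masks[[i]] <- mask
  }
  list(image = gray_image(m), masks = masks)
}

random_rgb <- function(h, w, seed = 1) {
  set.seed(seed)
  rgb_image(array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3)))
}

# Spot objects built by hand (0-based pixel coordinates)
manual_spot <- function(pixels) {
  structure(list(pixels = pixels, area = nrow(pixels)), class = "spot")
}

test_grid <- function() grid_spec(3, 3, pitch = 34, origin = c(24, 24), expected_radius = 10)
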