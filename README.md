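# aminoblot

Quantification of free-amine concentration maps from scanned ninhydrin
sensor papers.

## The problem

Root exudates — amino acids, sugars, organic acids released from growing
root surfaces — are hard to localize. One low-cost approach blots seedling
roots against paper printed with ninhydrin, a colorimetric indicator that
turns purple on contact with free –NH₂ groups. Scanning the developed
paper on a flatbed scanner yields an image in which darker pixels mean
more free amine. `aminoblot` turns such scans (and ground-truthed
synthetic stand-ins for them) into calibrated, per-pixel concentration
maps, for plant biologists who want spatial estimates of exudate
production without specialized imaging hardware.

## The model

Every color image is reduced to a weighted intensity

```
I = 0.30 R + 0.59 G + 0.11 B
```

Each sensor paper carries a printed 3 × 3 calibration grid spotted with a
mock exudate at three standards (1.71, 3.41, 4.71 mM free amine). Spot
mean intensities are screened with tight Tukey fences computed per
concentration across the batch (flag if outside `[Q1 − 0.5·IQR,
Q3 + 0.5·IQR]`); a paper with ≥ 2 flagged spots at a single concentration
is discarded. The retained spots fit an ordinary least-squares calibration

```
I = slope · c + intercept        (reference: I = −20.98 c + 241.71)
```

whose inverse `c = (I − intercept)/slope`, clamped to [0 mM, top
standard], converts every pixel to a concentration. The 95% confidence
band of the line, divided by |slope|, gives the concentration resolution
at each standard. Supporting arithmetic covers root growth rates
(`R_D = (L_{D+2} − L_D)/2` from segmented-line root traces), mock-exudate
free-amine accounting (the 70X recipe totals 23.9 mM), multiply-blend
root/blot overlays, and two-way ANOVA + Tukey HSD detection-limit
analysis.

All image I/O (8-bit PNG, uncompressed TIFF) is implemented in base R —
no image packages required.

## Worked example

```r
library(aminoblot)

batch  <- make_calibration_batch(n_papers = 10, noise_sd = 3,
                                 outlier_papers = c("P03", "P07"), seed = 42)
screen <- flag_outlier_papers(batch$spots)
cat("removed papers:", paste(screen$removed, collapse = ", "), "\n")
#> removed papers: P01, P03, P07

kept  <- batch$spots[batch$spots$paper_id %in% screen$retained, ]
model <- fit_calibration(kept)
model
#> Calibration: intensity = -21.1102 * conc + 242.1710
#>   n = 63 spots, R^2 = 0.9872, p(slope) = 2.12e-59
#>   residual SE = 3.0061, 95% CI level, clamp at 4.71 mM

res <- estimate_resolution(model, c(1.71, 3.41, 4.71))
cat(sprintf("resolution: %.2f mM\n", res$mean_range))
#> resolution: 0.10 mM
cat(sprintf("intensity 200 -> %.2f mM\n", intensity_to_conc(model, 200)))
#> intensity 200 -> 2.00 mM

obs <- make_sensitivity_batch(seed = 42)
cat(sprintf("detection limit: %.2f mM\n", detection_limit(obs)))
#> detection limit: 0.14 mM
```

The two designated outlier papers are recovered (P03, P07); P01 is a
false positive of the deliberately aggressive k = 0.5 screen — expected
behavior, not a bug (the original screening retained only 20 of 30 real
papers). The fitted line matches the generating line within noise; the
0.10 mM resolution reflects 63 clean synthetic spots, much tighter than
scanned papers achieve. The detection limit equals the fixture's
generating threshold, 0.14 mM (140 µM).

Image pipeline in one pass:

```r
fx    <- make_blot_image(trace = cbind(c(20, 150, 285), c(170, 185, 175)),
                         profile = c(4.2, 2.5, 1.0), seed = 1)
gray  <- to_gray(fx$image)
spots <- detect_grid(gray, grid_spec(3, 3, pitch = 34, origin = c(24, 24),
                                     expected_radius = 10))
cmap  <- concentration_map(gray, model)
write_png(render_heatmap(cmap), "heatmap.png")
write_png(overlay(make_root_scan(fx$truth$trace), fx$image), "overlay.png")
```

## Command line

```sh
Rscript inst/cli/aminoblot synth     --out-dir run1 --seed 1 --outliers P02
Rscript inst/cli/aminoblot calibrate --spots run1/batch.csv --out-dir run1
Rscript inst/cli/aminoblot quantify  --image run1/blot.png --model run1/calibration.json --out-prefix run1/q
Rscript inst/cli/aminoblot overlay   --root run1/root.png --blot run1/blot.png --out run1/overlay.png
Rscript inst/cli/aminoblot growth    --lengths lengths.csv --out rates.csv
Rscript inst/cli/aminoblot lod       --observations obs.csv --out lod.csv
```

Exit codes: 0 success, 2 usage/config error, 3 data/validation error.

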