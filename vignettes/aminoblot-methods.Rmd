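---
title: "Methods: calibrated free-amine mapping from ninhydrin blot papers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated free-amine mapping from ninhydrin blot papers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aminoblot)
```

## Scope and model

`aminoblot` implements the analysis side of a blot-based root-exudate
assay: seedling roots are pressed against paper printed with ninhydrin,
which develops purple in proportion to free-amine contact; the dried
paper and the seedling are scanned, and images are analyzed to localize
and quantify exudate production. Everything downstream of the scanner is
in scope — intensity arithmetic, spot segmentation, outlier screening,
calibration, inverse prediction, heatmaps, overlays, growth rates,
recipe accounting, and significance testing. The wet-lab protocol,
scanner settings and automatic image registration are not.

The core signal model is linear in the tested range:

$$I = \beta_1 \, c + \beta_0, \qquad
I = 0.30R + 0.59G + 0.11B \in [0, 255],$$

with $c$ the free-amine concentration in mM. The reference line, used as
the default for synthetic data, is $I = -20.98\,c + 241.71$: blank paper
scans near 242, and each mM of free amine darkens a developed spot by
about 21 intensity units. Inverse prediction
$\hat c = (I - \beta_0)/\beta_1$ is clamped to $[0, c_{\max}]$ with
$c_{\max}$ the top calibration standard (4.71 mM by default): pixels
brighter than blank carry no analyte, and pixels darker than the top
standard's expected intensity are reported at the ceiling rather than
extrapolated outside the calibrated range.

## One grayscale definition

The upstream workflow used two tools with two grayscale conversions
(a weighted-channel measurement and a desaturation step for overlays).
The package deliberately uses the single weighted sum
$0.30R + 0.59G + 0.11B$ everywhere — measurement, calibration and
overlay rendering share one intensity scale, so a value measured on a
spot and a value rendered in an overlay are directly comparable.
Intensities are carried as real numbers end to end; quantization to
8 bits happens only at image export, with one stated rounding rule
(round half away from zero), which is itself tested.

No gamma correction is applied: nothing in the source workflow indicates
the scans were gamma-corrected, and applying a correction we cannot
verify would silently bend the calibration line.

## Spot segmentation

The interactive magic-wand selection is reproduced as a seeded flood
fill: the maximal connected region around the seed whose intensities
stay within `tolerance` of the *seed pixel's* value. Measuring deviation
from the seed (not from a running region mean) is the simplest
reproducible contract and matches common wand tools. Defaults: tolerance
20 intensity units, 8-connectivity; both are free parameters because no
tolerance is recoverable from a manual workflow.

Calibration grids are located automatically: global threshold →
connected components → area filter ($[0.25, 4]\times$ the expected disk
area) → assignment to the nearest expected grid center within half the
grid pitch, in row-major order. The default threshold policy,
`"background"`, takes the modal rounded intensity (a blot paper is
mostly background) and cuts 10% (at least 8 units) below it. Otsu's
method is available but is *not* the default: on realistic blot images
the background class dominates and Otsu absorbs the faintest standard
(1.71 mM, ~36 units below blank) into it, which we observed directly on
noise-free synthetic grids. A fixed numeric threshold is also accepted.

## Outlier-paper screening

For each standard concentration, all papers' replicate spots are pooled
and Tukey fences $[Q_1 - k\,\mathrm{IQR},\; Q_3 + k\,\mathrm{IQR}]$
computed with $k = 0.5$; a paper is discarded when at least 2 of its
spots at a single concentration are flagged. Quartiles use linear
interpolation of order statistics (R's type 7, the spreadsheet default);
the hinge method is available as an option because hinge choice moves
fence placement and the source workflow does not pin it down. Fences are
pooled across the whole batch in one pass (the 3-, 5- and 7-day papers
jointly); per-day screening is a caller-side choice of batch.

**Known red acceptance criterion.** The $k = 0.5$ fence is aggressive by
construction: for clean Gaussian spots the population fence sits at
$\mu \pm 1.349\sigma$, so ≈17.7% of clean spots are flagged and a clean
paper has ≈23% probability of hitting ≥2 flags at one of three
concentrations. In a 10-paper batch with 2 designed outliers that means
≈1.6 false removals per batch and ≈55% precision. The acceptance
criterion demanding ≥95% precision at $k = 0.5$ is therefore not
attainable in the stated world — consistent with the original screen
retaining only 20 of 30 real papers — and the test is left failing
rather than quietly loosened. Recall of designed +60-unit outliers is
100%.

## Calibration and intervals

The calibration is ordinary least squares of spot mean intensity on
concentration, fitted with `lm()` and verified in the test suite against
closed-form normal-equation arithmetic to 1e-9. The stored model carries
$n$, residual SE, $\bar x$ and $S_{xx}$, so confidence intervals are
reproducible from the serialized JSON alone:

$$\hat y(x) \pm t_{1-\alpha/2,\,n-2}\; s
\sqrt{\tfrac1n + \tfrac{(x-\bar x)^2}{S_{xx}}}.$$

This is the band for the *mean response* (the regression line), matching
the source's description; a prediction-interval option exists but is off
by default. Dividing the band's intensity width by $|\beta_1|$ converts
it to a concentration range per standard; the mean across standards is
the reported quantification resolution. The printed resolution figures
in the source (1.0–1.6 mM) are not exactly band-width ÷ |slope| of the
printed intensity ranges (19/20.98 ≈ 0.91), so the package documents its
formula rather than matching those two numbers. Two-sided slope p-values
are reported at machine precision; a printed "p = 0.0" is treated as
underflow.

**Units.** The source text prints the standards once as µM, but the
recipe arithmetic, the figure scales and the calibration line are only
coherent in mM (at µM scale the fitted line would predict negative
intensity above ~12 µM). mM is used throughout.

## Visualization

Heatmaps map concentration linearly onto a perceptually uniform
"viridis" ramp (≥64 stops, via `grDevices::hcl.colors`) spanning 0 mM to
the top standard, so renderings of different papers share one scale.
Because the palette is a package choice rather than an upstream fact,
renderings carry a legend bar (tick marks and bitmap-font labels at the
standards) by default, plus a JSON sidecar with scale bounds, palette
name and calibration provenance. Rendering is a pure function: identical
inputs give bit-identical PNGs. Over- or under-exposed papers can be
compared against their own on-paper grid instead of the global scale;
that choice is exposed to the user, not auto-detected.

Overlays mirror the manual workflow: the root scan is desaturated, the
blot layer is moved by a *user-supplied* integer offset and rotation
(nearest-neighbor resampling, so no intensities are invented before
blending) and composited with a multiply blend,
`round(base · layer / 255)` per channel. Registration is deliberately
manual; automatic root-to-blot registration is a non-goal.

## Synthetic fixtures: what they emulate and what they do not

`make_calibration_batch`, `make_blot_image` and `make_root_scan` are
pure functions of parameters + seed and serialize their ground truth.
Defaults state the emulated world once:

* generating line $-20.98\,c + 241.71$, standards {1.71, 3.41, 4.71} mM,
  3 replicates per standard, 3 × 3 grid — the published calibration
  setup;
* spot noise σ = 3 intensity units for batch tables (the batch screening
  criterion states this), σ = 5 for the CI-coverage criterion, per-pixel
  σ configurable for images;
* designated outlier papers get a +60-unit shift at one standard —
  roughly a 3 mM quantification error, an unmistakably failed paper;
* blot images synthesize a purple tint by solving, per target gray value
  $t$ (quantized to 0.01), integer $30R + 59G + 11B = 100t$ with
  $R, B \gtrsim G$ — the weighted intensity of the rendered pixel equals
  the gray target *exactly* wherever the 0.01 grid is representable
  (everywhere except within ~0.3 units of pure white/black, where the
  nearest neutral gray is used). The gray contract, not the hue, is what
  downstream code consumes; this is why noise-free concentration
  round-trips hold to < 1e-3 mM through 8-bit RGB files.

The sensitivity fixture for detection-limit tests puts no effect below a
generating threshold (0.14 mM by default, the reported sensitivity) and
the calibration-line response at and above it, with between-paper offsets
(σ = 1) and within-paper spot noise σ = 2. The noise level is a design
choice made once: the smallest real effect (20.98 × 0.14 ≈ 2.9 units) is
then ≈6 standard errors of a group difference at n = 36 per level, so
the fixture's ground-truth threshold is statistically identifiable —
a fixture whose truth cannot be recovered would test nothing.

What the generators do *not* emulate: paper texture, wrinkles, uneven
development, scanner vignetting, or spatially correlated noise. A green
round-trip test establishes that the arithmetic pipeline is faithful; it
does not establish robustness to real-scan artifacts.

## Statistics

Significance testing is a fixed-effects two-way ANOVA (primary factor +
paper, additive) with Tukey HSD pairwise comparisons, via `aov()` and
`TukeyHSD()`; the source names two factors and no interaction, so the
interaction term is off by default but available. α defaults to 0.01.
The detection limit is the smallest concentration significantly
different from the 0 mM control *provided every larger concentration is
too* — an isolated significant level above a non-significant gap does
not set the limit. Zero-variance degenerate data yields NaN p-values,
which count as "not significant".

Stability analyses (day as the primary factor) reuse the same routine —
observations with a `day` column instead of `concentration`.

## Numerical and design choices

* Image I/O is implemented in base R: PNG IDAT streams are zlib, which
  `memCompress`/`memDecompress(type = "gzip")` emit and accept; chunk
  CRC32s are table-driven; TIFF is baseline uncompressed. Only 8-bit
  gray/RGB are supported and alpha channels are rejected outright —
  calibrated intensities need unambiguous channel semantics.
* Coordinates are 0-based (row, col) from the top-left at all public
  interfaces (CSV tables, seeds, offsets), matching image conventions.
* Grid cells are ordered row-major from the top-left; row $i$ of the
  grid carries standard $i$.
* Spots touching the image border are measured but flagged
  (`touches_border`), not dropped.
* Configuration is JSON (no YAML parser in the supported dependency
  set); unknown keys are rejected.
* The end-to-end unbiasedness property test runs 120 seeds rather than
  200 to stay inside the suite's time budget; the Monte-Carlo margin at
  120 seeds is still ≈20× smaller than the asserted bound.

## Known limitations

* Grid detection assumes a flat scan roughly aligned with the template;
  deformable or perspective-corrected grid fitting is out of scope.
* Per-paper individual calibration is supported by calling
  `fit_calibration` on one paper's spots, but the default path pools the
  retained batch, as in the source analysis.
* The k = 0.5 screen's false-positive rate (above) means retained-paper
  counts understate true paper quality; treat the screen as a
  conservative quality gate, not a classifier.
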