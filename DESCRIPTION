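Package: aminoblot
Title: Quantification of Free-Amine Maps from Ninhydrin Sensor Papers
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying free-amine concentrations from scanned
    images of ninhydrin-based colorimetric sensor papers blotted against
    seedling roots. Implements weighted RGB grayscale conversion, seeded
    flood-fill spot segmentation of calibration grids, Tukey-fence rejection
    of outlier papers, linear calibration with confidence intervals and
    inverse prediction, per-pixel concentration heatmaps, multiply-blend
    root/blot overlays, root growth-rate arithmetic, mock-exudate free-amine
    accounting, and two-way ANOVA with Tukey HSD for limit-of-detection
    analysis. Includes a ground-truthed synthetic fixture generator and a
    command-line interface. Reads and writes 8-bit PNG and uncompressed TIFF
    without external image libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
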