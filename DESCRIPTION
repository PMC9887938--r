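Package: memtension
Title: Optical-Trap Tether Force and Traction Force Microscopy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for measuring effective membrane
    tension and cytoskeletal contractility from optical-tweezers and traction
    force microscopy (TFM) recordings. Covers power-spectrum trap calibration
    (Lorentzian fit to the Brownian motion of a trapped bead), conversion of
    membrane tether pull recordings into calibrated force-time curves with
    protocol phase segmentation and extraction of peak and steady-state tether
    forces, PIV-style bead-image displacement estimation, regularized
    Fourier-transform traction cytometry on an elastic half-space, net-force
    integration over regions of interest, and the nonparametric group
    comparisons (exact Mann-Whitney, Kruskal-Wallis with Dunn or
    Tukey-on-ranks post hoc) used to compare experimental conditions. A
    synthetic-data module generates every pipeline input (Ornstein-Uhlenbeck
    bead traces, tether pull curves, TFM image pairs) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
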