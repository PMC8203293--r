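Package: mechanoscape
Title: Multiscale Quantification of Tumor Mechanics and T Cell Motility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for multiscale tumor-mechanics studies:
    shear-wave elastography stiffness maps (ROI summaries, stiff-area
    fractions at a kPa threshold, normalized stiffness time series, caliper
    tumor volumes), collagen fiber architecture from second-harmonic
    generation images (ridge-based fiber tracing, width, length, curvature
    ratio, orientation coefficient of variation, Sirius-red packed-fiber
    fraction, crosslink fluorescence in SHG-positive regions), Hertzian
    spherical-indenter fitting of AFM force-indentation curves, 3D T-cell
    track motility statistics with depth and duration filtering, and a
    per-subject stiffness-versus-motility correlation layer. Includes seeded
    synthetic-data generators with known ground truth for every stage and an
    end-to-end study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    graphics,
    grDevices,
    tools,
    utils,
    tiff,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
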