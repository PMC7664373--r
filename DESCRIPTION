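Package: holoplankton
Title: Off-Axis Holographic Microscopy Simulation, Reconstruction and
    Single-Generator Diatom Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative phase imaging of microplankton by
    off-axis digital holography. Simulates holograms of phase-only phantom
    slides, demodulates and numerically refocuses them by the angular
    spectrum method with Tamura-coefficient autofocus, segments individual
    objects from wrapped phase maps (Otsu threshold plus hole filling),
    expands one wrapped phase image per class into a large training set via
    a wrap-preserving scale/rotation/phase-bias augmentation lattice, and
    trains max-voting ensembles of small image classifiers, so that a
    species classifier can be learned from a single captured hologram per
    class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
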