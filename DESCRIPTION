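Package: spici
Title: Spatial Proteomics Informed Cell Identification for Spot-Based
    Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates multiplexed protein imaging (PhenoCycler/CODEX)
    with spot-based spatial transcriptomics (Visium). Segmented cells are
    quality-filtered, log-scaled and typed by marker-subset scoring against
    a 17-type immune/tumor panel; the nuclear-stain image is registered to
    the histology image by mutual-information affine (optionally spline-grid)
    alignment; typed cells are mapped into spot coordinates and aggregated
    into per-spot cell-type compositions, with dominant-label evaluation
    against reference annotations.  Also provides a spot-level
    ligand-receptor co-expression permutation test against random gene-pair
    backgrounds with significant-spot ranking, and a synthetic-data module
    generating every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
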