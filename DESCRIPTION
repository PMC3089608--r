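Package: zonestack
Title: Quantitative Image Analysis of Multi-Zone Paper-Supported 3D Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.invalid",
    role = c("aut", "cre"))
Description: Analysis pipeline for fluorescence gel-scanner images of
    wax-patterned paper sheets used as stackable multi-zone 3D cell culture
    arrays. Detects 96-zone grids on distorted wet-paper scans by fitting
    fixed-radius circles to wax/paper autofluorescence edges, quantifies
    background-corrected zone intensities, calibrates fluorescence intensity
    to cell number, computes half-radial intensity profiles and assembles
    replicate/layer heat maps, and derives stack-level growth, condition
    comparison, and cell-migration statistics. Includes a synthetic sheet-scan
    generator with known ground truth (non-rigid warps, cell-free rims,
    wax/paper contrast, additive noise) so that every stage is testable
    without real scans, and a command-line interface wiring the stages into a
    reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
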