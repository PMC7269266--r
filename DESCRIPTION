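Package: pelletmetrics
Title: Quantitative Morphology and Viability Analysis of Filamentous Pellets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification stack for filamentous biopellets from submerged
    cultivations: segmentation and macro-morphological measurement of pellets
    in calibrated brightfield micrographs (equivalent-circle diameter,
    circularity, Feret extremes, number- and volume-weighted size
    distributions), live/dead area quantification of stained pellet slices
    imaged by confocal microscopy, pulse-shape analysis of spatially resolved
    flow-cytometry signal profiles (compactness, viable layer, viability and
    autofluorescence factors), biomass-specific productivity kinetics, and
    per-day one-way ANOVA comparisons between cultivation conditions. A
    seeded synthetic-data generator produces brightfield images, stained-slice
    channel pairs, pulse profiles and cultivation time series with known
    ground truth so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    pracma,
    jsonlite,
    rlang,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png,
    withr
Config/testthat/edition: 3
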