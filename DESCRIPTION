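Package: dyadscape
Title: Quantitative Image Analysis of Cardiomyocyte T-Tubules, Dyads and
    Local Calcium Release
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measurement pipelines for cardiomyocyte subcellular structure
    and excitation-contraction coupling from fluorescence microscopy.
    Segments and skeletonizes the t-tubule network from membrane-dye
    confocal images and decomposes it into transverse and longitudinal
    elements; quantifies dyadic protein organization from two-channel
    immunostains (Manders fractional overlap with automatic Costes
    thresholds, orientation-resolved colocalization via directional
    territory masks, dyadic density, nearest-neighbour distance maps);
    maps calcium-release dyssynchrony and local transient timing from
    rapid 2D time-lapse recordings; measures the electrically activated
    fraction of the tubule network from voltage-dye recordings; and
    computes surface-topography indices (Z-groove index, t-tubule opening
    fraction) from annotation tables. A seeded synthetic-data module
    simulates developing, adult and failing phenotypes with ground-truth
    sidecars so every measurement stage is verifiable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    EBImage,
    igraph,
    jsonlite,
    withr,
    class
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
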