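Package: Ki67Hotspot
Title: Automatic Hot-Spot Selection in Ki-67 Stained Whole-Slide Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Context-aware selection of Ki-67/MIB-1 hot-spot fields of view
    in whole-slide images of meningioma specimens. Builds an artifact-aware
    specimen map, eliminates hemorrhages, tissue folds and stained vessel
    walls using Unser sum/difference-histogram textures, rotation-invariant
    local binary patterns, Fisher feature ranking and a two-stage Gaussian
    support vector machine cascade, extracts immunopositive cell markers by
    the inverse extended-regional-minima transform, and selects spatially
    diversified hot-spot fields with a gradual-extinction distance penalty.
    Includes a seeded synthetic-slide generator with full ground truth,
    Spearman and Bland-Altman agreement statistics, and a command-line
    driver for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    e1071,
    png,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBiology, Classification, Software, Visualization
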