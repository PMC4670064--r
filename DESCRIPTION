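Package: nicheshift
Title: Presence-Background Niche Models and Realized Niche Shift Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for climate-based invasion risk analysis: derivation and
    collinearity screening of bioclim-style predictors (including growing
    degree-days) from monthly climate grids, occurrence cleaning with
    grid-cell deduplication and spatial thinning, kernel sampling-bias
    surfaces and background sampling, a penalized maximum-entropy
    presence-background model with linear/quadratic/product/hinge features
    and AICc model selection, cross-validated AUC and partial-ROC
    evaluation, PCA-based niche overlap (Schoener's D) with equivalency and
    similarity randomization tests and niche-dynamics indices, invasion
    stage classification from paired regional and global predictions, and a
    seeded virtual-species generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
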