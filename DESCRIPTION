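Package: glimap
Title: Observer-Independent Cytoarchitectonic Mapping from Gray Level Index Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for observer-independent cytoarchitectonic mapping of the
    cerebral cortex. Converts cell-body images into gray level index (GLI)
    images measuring the volume fraction of stained cell bodies, computes
    equidistant cortical traverses between the layer I/II and layer VI/white
    matter contours with a Laplace-field model, extracts depth-normalized
    laminar GLI profiles, and detects areal borders as significant maxima of a
    sliding-window Mahalanobis distance between 10-dimensional profile feature
    vectors (Hotelling's T-squared with Bonferroni correction, multi-block-size
    and multi-section acceptance). Also provides mean areal profiles, Ward
    hierarchical clustering of areas, canonical discriminant projections,
    shrinkage-corrected area volumetry, and population-level probability and
    maximum probability maps with centers of gravity. Includes a synthetic
    cortex generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    mgcv,
    RNifti,
    jsonlite,
    ape,
    png,
    tiff,
    tools,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
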