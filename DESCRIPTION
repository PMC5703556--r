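Package: uavCrowns
Title: Object-Based Delineation and Classification of Individual Tree
    Crowns from UAV Imagery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Delineates individual tree crowns from very-high-resolution
    three-band (blue, green, red-edge) UAV orthomosaics together with
    photogrammetric surface and terrain models, and classifies each crown
    into four dry-forest classes (Sapote, alive Algarrobo, dead Algarrobo
    and the Overo shrub). The workflow is object-based: a multiresolution
    region-merging segmentation produces object candidates, vegetation is
    masked by red-edge and blue-green band-ratio indices, isolated crowns
    are separated from crown clusters by shape and extent, clusters are
    de-clustered by local-maximum seeding (canopy-height maxima for green
    vegetation, non-photosynthetic-vegetation-index maxima for leafless
    canopies) followed by seeded region growing, and crowns are classified
    by threshold rules on object features. Accuracy assessment (plot-level
    detection rates, error matrix with producer's/user's/overall accuracy,
    detection-rate-adjusted abundances) and 50 m fishnet landscape metrics
    (density, crown cover, mortality) are included, together with a
    synthetic-scene generator that renders labelled test scenes with the
    spectral and structural signatures the classifier assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, grDevices, tiff, jsonlite, yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
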