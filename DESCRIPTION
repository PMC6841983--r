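Package: retmorph
Title: Regional Morphometry of Retinal Microvascular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the geometry of retinal microvascular networks from
    binary vessel-segmentation masks, region by region. Extracts square or
    circular regions of interest centred on the optic disc and the macula,
    skeletonizes the vessel mask by topological thinning, and measures
    multi-origin box-counting fractal dimension, fixed-grid lacunarity and
    skeleton vessel density. Includes pixel-to-micrometer calibration from
    optic-disc dimensions, caliber estimation via the Euclidean distance
    transform, diameter-based branching-generation assignment, a synthetic-data
    module (exact-dimension fractal fixtures and simulated vascular trees with
    a foveal avascular zone), and the group statistics used in regional
    studies of vascular remodelling (two-sample t-tests, one- and two-way
    ANOVA with Tukey post-hoc tests and compact letter displays).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
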