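Package: swaseg
Title: Multilevel Weighted-Aggregation Segmentation for Bright-Field Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments 2D bright-field microscope images and 3D space-time image
    stacks by multilevel weighted aggregation: the pixel affinity graph is
    recursively coarsened with the first pass of classical algebraic-multigrid
    (Ruge-Stuben) C/F splitting, coarse-level couplings are formed by Galerkin
    triple products and rescaled by block mean intensity and by multilevel
    intensity-variance texture features, and aggregates are frozen into final
    segments by a scale-invariant saliency measure that normalizes the
    similarity-weighted boundary length and area of a block by their unweighted
    counterparts. A bottom-up sharpening pass turns the overlapping salient
    blocks into a unique per-pixel label map; applied to temporal stacks the
    labels form space-time "object tunnels" usable for cell tracking. Includes
    seeded synthetic fixtures (uniform shapes, equal-mean texture pairs, moving
    and dividing blobs) with ground-truth masks, TIFF/PNG label output, JSON
    diagnostics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    Rcpp,
    jsonlite,
    optparse,
    png,
    tiff,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
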