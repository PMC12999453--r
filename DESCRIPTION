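Package: fibrefab
Title: Fiber Anisotropy Mapping from Segmented Volumes via Mean
    Intercept Length Fabric Tensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies three-dimensional fiber orientation and degree of
    anisotropy in segmented (binary or labeled) voxel volumes, such as
    micro-CT scans of fibrocartilage and trabecular bone.  Computes
    directional Mean Intercept Length (MIL) profiles, fits MIL fabric
    tensors, and maps primary eigenvectors, eigenvalue magnitudes and a
    0-1 anisotropy index in sliding windows to produce an orientation
    vector field.  Provides axial directional statistics (dominant-axis
    fractions, anatomical-plane rose histograms weighted by fiber
    frequency or summed magnitude, regional anisotropy contrasts),
    trabecular-style morphometry (volume, extents, local thickness and
    separation by the largest-inscribed-sphere definition), synthetic
    phantom generators with known ground truth for validation, TIFF
    stack input/output, and a deterministic end-to-end pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
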