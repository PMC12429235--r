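Package: tracheasr
Title: Trachea Lumen Surface Roughness from CT Airway Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the roughness of the trachea lumen surface from a
    3D binary airway-tree segmentation. The trachea is isolated between a
    few millimetres below the top slice and the carina, its inner surface
    is unrolled onto an angle-by-axial-position radius grid and decomposed
    into shape, curvature and total topological maps, and each map's
    fractal dimension is estimated by integer-ratio differential box
    counting and reported as a surface-roughness percentage (SR_S, SR_C,
    SR_T). Also computes the tracheal index (minimum coronal/sagittal
    diameter ratio) and the LAA-950 emphysema measure, and ships a phantom
    generator (elliptical tubes, bifurcations, fractional-Brownian wall
    texture) so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    igraph,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
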