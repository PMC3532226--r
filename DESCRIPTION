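Package: layerquant
Title: Quantification of Spatial Gene Expression Along the Embryonic Cell Layer
Version: 1.0.0
Authors@R: person("layerquant", "developers", role = c("aut", "cre"),
    email = "maintainers@layerquant.example.org")
Description: Toolchain for quantifying whole-mount in situ hybridization
    images of two-layered (diploblast) embryos such as the sea anemone
    Nematostella vectensis. Embryo geometries are represented as paired
    closed cubic-spline rings placed on the inner and outer cell-layer
    boundaries; the ribbon between them is decomposed into parallel
    quadrilateral segments whose mean stain intensities yield a 1D
    expression profile along the cell layer. Profiles can be repaired,
    smoothed, baseline-corrected, symmetrized and standardized to a
    normalized -50..+50 coordinate with maximum 100. Three-dimensional
    expression arrays are reconstructed either from two perpendicular
    views by minimum mixing or from a single view by weighted averaging
    along circular arcs about a drawn symmetry axis, then sliced through
    the primary body axis into 2D expression landscapes. Standardized
    profiles are compared by Pearson correlation and grouped by
    average-linkage hierarchical clustering. Synthetic phantom embryos
    with analytically known geometry and expression provide ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    ggplot2,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
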