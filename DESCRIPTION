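Package: pvdmorph
Title: Automated Tracing and Morphometry of C. elegans PVD Dendritic Arbors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting and quantifying the architecture of the
    highly arborized PVD neuron of Caenorhabditis elegans from 2-D
    fluorescence maximum-intensity projections. The pipeline classifies
    pixels as neuron or background, reduces the classification to a
    topological skeleton, fits the neuron with chained rectangular masks
    (a simplified region-based active-contour model) guided by the
    skeleton, fits three-way junctions as circles with radially emanating
    rectangles, maps every traced element into worm-intrinsic coordinates
    (arclength s, azimuth phi, midline orientation theta), clusters
    elements into four morphological classes, and characterizes junction
    geometry by Monte Carlo simulation and grid fitting of intrinsic
    angle triplets. A synthetic worm-image phantom generator with exact
    ground truth makes every stage testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    MASS,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
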