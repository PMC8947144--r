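Package: sxtcell
Title: Post-Processing and Mesoscale Spatial Analysis of Soft X-Ray Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for assembling and analysing organelle segmentations of
    single-cell soft X-ray tomograms. Provides readers and writers for MRC and
    multi-page TIFF volumes of linear absorption coefficient (LAC) values,
    slice/patch preprocessing, three fusion algorithms (per-voxel multi-view
    majority voting of semantic masks, 2D-to-3D instance linking by
    intersection-over-union between adjacent slices, and priority-based merging
    of organelle masks into a single cell scene), segmentation evaluation
    metrics (Dice, distance-based instance recall, AP50, contrast ratios), and
    mesoscale spatial statistics: an 8-shell partition of the cytosol by
    normalized nucleus-to-membrane depth, radial distribution functions of
    vesicle centers, mitochondria voxels and vesicle-mitochondria contacts, and
    per-vesicle radial LAC profiles. A synthetic phantom generator emulating an
    insulin-secreting beta cell makes every stage testable without tomograms or
    trained networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    ggplot2,
    generics,
    rlang,
    tiff,
    yaml,
    jsonlite,
    withr,
    stats,
    tools,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
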