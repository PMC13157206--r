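Package: rtssfidelity
Title: Round-Trip Fidelity Assessment for DICOM RT Structure Sets
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how loading and re-exporting DICOM Radiotherapy
    Structure Sets (RTSS) displaces contour boundaries. Provides a minimal
    RTSS reader/writer with controllable coordinate precision, generators
    for analytically defined structure pairs (sparse and dense cuboids and
    octahedra, multi-region fixtures), a simulator of contouring-system
    re-export behaviours (decimal truncation, path resampling, mask
    round-trips, small-region removal), slice-wise vertex-displacement
    analysis with cumulative distance distributions and topology-change
    detection, and a suite of contour similarity measures: normalised added
    path length (nAPL) and surface Dice (sDSC) at voxel-relative tolerances,
    volumetric Dice (vDSC), the 2D Hausdorff distance family, and 2D/3D mean
    surface distances via marching-tetrahedra surface extraction from a
    signed distance transform.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
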