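Package: rhizoflow
Title: Image-Based Homogenisation of Soil Hydraulic Properties from
    Three-Phase Voxel Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes hydraulic properties of partially saturated soil
    directly from three-phase (solid/water/air) voxel images. Provides
    synthetic generators for sand-like and clay-like pore architectures,
    quasi-static morphological drainage over a matric-potential schedule,
    three-phase threshold segmentation with noise-object exclusion,
    representative-elementary-volume (REV) subsampling with dyadic volume
    series and mirror reflection, a staggered-grid Stokes cell-problem
    solver that upscales pore-scale flow to a permeability tensor and
    hydraulic conductivity, pore-population metrics (counts, volumes,
    isosurface areas), and van Genuchten water-retention and relative
    conductivity fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    tiff,
    yaml,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
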