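Package: cellcompr
Title: Quantification of Mechanical Cell Competition in Stem Cell Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification methods for cell-competition experiments in
    human pluripotent stem cell cultures: per-cell local density from
    Delaunay triangulation of nuclei centroids, confrontation-assay border
    profiling of apoptosis versus distance to the population interface,
    nuclear-to-cytoplasmic marker ratios from dilation/erosion ring masks,
    Hertz spherical-indenter fits of AFM force-indentation curves,
    co-culture competition metrics (growth curves, subline ratios, density
    titrations), and qPCR relative copy-number estimation by 2^-ddCq.
    Includes a synthetic-data generator emulating the statistical structure
    of each input so every stage carries a ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    EBImage,
    minpack.lm,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
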