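Package: nucsize
Title: Automated Nuclear Size Estimation in Calibrated 3D Fluorescence Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates nuclear cross-section areas and volumes in spatially
    calibrated confocal z-stacks of DAPI-stained plant root sections using
    three automated methods: per-slice blob detection with z-linking and
    Cavalieri slab summation (slice-track), substack projection with
    circularity- and size-gated particle analysis (round-surface detection),
    and global thresholding with 3D connected-component voxel volumetry
    (object counting). Includes a synthetic phantom generator with exact
    ground truth, Sturges-rule volume classing with putative ploidy labels,
    median tests, lognormal/gamma distribution fitting, a bootstrap
    refit-and-regenerate moment-statistics procedure, and Kruskal-Wallis with
    Dunn's Bonferroni-corrected post-hoc comparisons.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    e1071,
    fitdistrplus,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
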