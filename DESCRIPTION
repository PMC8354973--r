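Package: octex
Title: Texture-Based Tissue Classification for Optical Coherence Tomography B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated discrimination of tumorous from healthy tissue in
    volumetric optical coherence tomography (OCT) scans. Implements the full
    analysis chain: region-of-interest segmentation of B-scans (median
    filtering, Canny edge detection, Otsu thresholding), tiling into 32x32
    sub-images, extraction of four texture-feature families (local binary
    patterns, gray-level run-length statistics, Haralick co-occurrence
    features and Laws texture energies) averaged per B-scan, z-score and
    principal-component preprocessing, and radial-basis support-vector-machine
    classification with grid search over cost and kernel width under tenfold
    cross-validation. A synthetic speckle-phantom generator provides
    ground-truth volumes with class-specific texture for testing and
    benchmarking without access to clinical scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
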