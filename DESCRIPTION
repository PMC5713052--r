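Package: corneaHSI
Title: Hyperspectral Image Enhancement and Classification of Corneal
    Epithelium Injuries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for visible-near-infrared hyperspectral cubes
    of the cornea: flat-field reflectance calibration against dark-current and
    white-reference frames, FFT-based template matching to locate the cornea,
    an image-enhancement chain (gamma adjustment, band-group selection by
    mutual information, grayscale erosion with a non-flat ball structuring
    element, Laplacian-of-Gaussian filtering, per-cube principal component
    analysis and principal-component difference imaging), first-order
    histogram texture features, and a from-scratch soft-margin support vector
    machine with a Gaussian radial basis function kernel evaluated by
    stratified cross-validation with ROC/AUC. Includes a synthetic-scene
    generator emulating unstained corneal-epithelium abrasions and a packaged
    25-eye histogram-feature table.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    png,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    e1071,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
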