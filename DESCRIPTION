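Package: conotex
Title: Crystallographic Texture Analysis for Biomineral EBSD and Raman Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies crystallographic preferred orientation in biomineral
    electron backscatter diffraction (EBSD) maps, with an emphasis on the
    apatite dental tissues of conodonts and other early vertebrates. Provides
    quaternion orientation arithmetic under hexagonal crystal symmetry,
    kernel-density orientation distribution functions (de la Vallee Poussin
    kernel), the Texture Index, the M-index from uncorrelated misorientation
    distributions, pole-figure densities in multiples of uniform density and
    the pole-figure texture index, threshold-based grain reconstruction,
    area-subsampling robustness analysis with non-parametric group statistics,
    and pseudo-Voigt fitting of the Raman v1-phosphate band with ranged major
    axis (model II) regression for diagenesis screening. Includes readers and
    writers for the CTF and ANG vendor text formats and a synthetic-data
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
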