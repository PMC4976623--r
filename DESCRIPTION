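Package: boneraman
Title: Chemometric Analysis of Bone Raman and SORS Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the mineral-to-collagen ratio of bone from
    Raman spectra, including transcutaneous spatially offset Raman
    spectroscopy (SORS) measurements. Provides iterative modified-polyfit
    fluorescence background removal, cosmic-ray despiking, band
    normalisation, band-target entropy minimisation (BTEM) recovery of
    per-subject bone spectra from mixed skin/lipid/bone signals, PCA-based
    collagen scoring with group-mean spectral reconstruction, and
    normal-theory diagnostic sensitivity and sample-size calculations.
    A synthetic-data generator produces excised-bone cohorts and in vivo
    SORS measurements with known ground truth so that every stage of the
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
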