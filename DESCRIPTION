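Package: zfqmri
Title: Quantitative MRI Relaxometry and Myelin Morphometry for Zebrafish
    Brain Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise T1/T2 relaxometry by gradient descent on multi-TR /
    multi-TE spin-echo series, landmark-based 2D rigid motion correction,
    skull-normalized brain morphometry, white-matter ROI intensity
    normalization, and perimeter-based G-ratio quantification from paired
    axon/myelin contours.  Includes a synthetic phantom generator (piecewise
    constant M0/T1/T2 compartments, Rician noise, injected rigid motion,
    fiber contour sets with known G-ratios) so the full pipeline can be
    exercised end-to-end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    minpack.lm,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
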