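Package: niceseg
Title: Nonlocal Intracranial Cavity Extraction from T1-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-template patch-based label fusion for intracranial
    cavity extraction from T1-weighted MRI volumes registered to a common
    stereotactic space. Implements nonlocal-means label fusion with
    structural-similarity patch preselection, an adaptive bandwidth, a
    bilateral (spatial plus intensity) patch weight, blockwise overcomplete
    voting, coarse-to-fine multiresolution refinement, tissue-anchored
    piecewise-linear intensity normalization, a synthetic head-phantom
    generator for validation, and Dice/sensitivity/specificity/volume
    evaluation metrics. Volumes are read and written as NIfTI-1 files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Rcpp, RNifti, jsonlite, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
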