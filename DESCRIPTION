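Package: pctqa
Title: Dosimetric and Radiomic Quality Assurance for Pseudo-CT in Brain
    Stereotactic Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-modal evaluation of MRI-derived pseudo-CT against planning
    CT for brain stereotactic radiotherapy. Provides geometry-aware 3-D volume
    handling with NRRD and NIfTI input/output, a synthetic head-phantom
    generator with analytic stereotactic dose, per-structure Hounsfield-unit
    statistics, dose-volume-histogram metrics with prescription and D95
    normalisation, 3-D gamma analysis (global and local normalisation),
    extraction of the 107 original-image radiomic features across seven
    families, EUD-logistic tumour control probability and
    Lyman-Kutcher-Burman normal-tissue complication probability from
    differential DVHs, and the paired nonparametric statistics (exact
    Wilcoxon signed-rank, Spearman correlation, mean absolute deviation) used
    to compare the two image types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
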