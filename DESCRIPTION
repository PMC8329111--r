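Package: segsim
Title: Spatial Similarity Metrics for 3D Segmentation Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes spatial similarity metrics between pairs of co-registered
    3D binary segmentation masks, as used to evaluate automated medical image
    segmentations against manually corrected references: volumetric Dice
    similarity coefficient, Jaccard index, surface Dice at a distance
    tolerance, percentile Hausdorff distances, average surface distance,
    added path length, false negative path length, and false negative volume.
    Includes NIfTI mask input/output, a nonparametric association pipeline
    (Shapiro-Wilk, Spearman, Mann-Whitney U, Kruskal-Wallis with Bonferroni
    post-hoc tests) relating metric panels to segmentation correction times,
    and a synthetic phantom-cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
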