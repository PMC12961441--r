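Package: ptv2fr
Title: Point-Transformer Segmentation and Phenotypic Trait Extraction for Sorghum Seedling Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Semantic segmentation of sorghum seedling point clouds (leaf, stem,
    pot) with a U-shaped point-transformer network whose attention blocks use
    multi-radius dual-coordinate attention and whose decoder output is refined
    by point-graph involution kernels gated by per-point entropy, trained with
    a composite loss of inverse-frequency weighted cross-entropy and multiclass
    Lovasz-softmax. Includes PLY input/output, furthest-point sampling,
    pot-level dataset splitting, training augmentations, per-class
    IoU/precision/recall/F1 reporting, a downstream trait pipeline (DBSCAN stem
    instancing, RANSAC+PCA stem axes, leaf dimensions, Delaunay leaf area, leaf
    area index), and a procedural generator of labeled seedling pots with
    analytically known traits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
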