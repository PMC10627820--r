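Package: canopyfuse
Title: Probabilistic Canopy-Height Mapping from Multispectral Imagery with
    Sparse LiDAR Supervision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Dense canopy-top-height regression from multi-band optical
    imagery with per-pixel predictive uncertainty. A fully convolutional
    residual network with separable convolutions predicts a Gaussian mean and
    variance per pixel and is trained with sparse supervision at scattered
    LiDAR footprint labels using the Gaussian negative log likelihood. Deep
    ensembles and repeated acquisitions are fused by inverse-variance
    weighting with full variance propagation (law of total variance).
    Includes square-root inverse-frequency reweighting for imbalanced height
    distributions with mean-head-only fine-tuning, accuracy and uncertainty
    calibration metrics (RMSE/MAE/ME/NME, height-balanced variants, UCE/AUCE),
    uncertainty-based filtering, GEDI-like canopy-top derivation from
    high-resolution canopy height models via circular max-pooling, a
    synthetic-scene simulator for end-to-end testing, and tiled raster
    inference with nodata conventions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    tiff,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'canopyfuse-package.R'
    'chm_compare.R'
    'ensemble.R'
    'evaluation.R'
    'geo.R'
    'map_pipeline.R'
    'model.R'
    'scene_io.R'
    'scene_sim.R'
    'training.R'
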