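Package: smlmfit
Title: Maximum-Likelihood Geometric Model Fitting for Single-Molecule
    Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits parameterized geometric models (rings, splines, tubes,
    discrete fluorophore arrangements, density images) to single-molecule
    localization microscopy (SMLM) coordinate data by maximum likelihood,
    weighting every localization by its own anisotropic precision. Provides
    AICc-based model selection, chained multi-step optimization, confidence
    intervals from the observed information, a realistic two-state fluorophore
    blinking simulator, reference-based and model-free particle averaging,
    pseudotime reconstruction of dynamic structures, depth-dependent axial
    distortion correction, and ring-kernel site segmentation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'models.R'
    'pdfcore.R'
    'fitting.R'
    'averaging.R'
    'locdata.R'
    'preprocess.R'
    'simulator.R'
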