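Package: wormupr
Title: Quantification of Mitochondrial Stress Reporters, TMRE Imaging,
    Lipidomics and Single-Worm qPCR in C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis stack for a C. elegans study of mitochondrial
    unfolded protein response (UPRmt) suppression by autophagy.
    Implements whole-animal fluorescence-reporter quantification
    (Triangle-threshold segmentation and group normalization),
    the mitochondrial TMRE segmentation workflow (rolling-ball
    background subtraction, rank filters, Hessian-eigenvalue tubeness,
    IsoData thresholding) with intensity-per-area readout, a gated
    statistical decision procedure (Shapiro-Wilk / Brown-Forsythe gates
    routing to t, Welch, ANOVA+Dunnett or Kruskal-Wallis+Dunn), an
    LC-MS lipidomics feature pipeline (QC presence/RSD filtering,
    protein and injection-order drift normalization, per-feature Welch
    tests, triacylglycerol sum-composition landscapes), single-worm
    qPCR variability analysis (delta-Ct expression, primer efficiency,
    coefficient-of-variation normalization), screen bookkeeping, and
    seeded synthetic-data generators with ground truth for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    mvtnorm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
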