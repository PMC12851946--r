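Package: spinepath
Title: Explainable Digital Pathology Pipeline for Vertebral Compression
    Fracture Subtyping and Risk Stratification
Version: 0.1.0
Authors@R:
    person("Spinepath", "Developers", email = "spinepath@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-testable digital pathology
    toolkit for vertebral compression fractures (VCF). Provides a seeded
    generator of H&E-like bone histology with planted ground truth
    (trabecular lattice, marrow adiposity, nuclei, tumor clusters,
    fracture clefts), slide preprocessing (Otsu tissue segmentation,
    Macenko stain normalization, overlapping tiling with artifact QC),
    bone histomorphometry (trabecular thickness/separation via
    distance-transform skeletons, adiposity, collagen fraction, nuclear
    eccentricity), an attention-based multiple-instance-learning slide
    classifier with Grad-CAM explanations, a gradient-boosted Cox risk
    model with exact tree-SHAP attributions and interactions,
    transcriptomic signature scoring (immune activity, RANKL axis,
    therapy-response), and a survival-statistics toolkit (Kaplan-Meier,
    log-rank, Cox, Harrell's concordance, bootstrap confidence
    intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    png,
    Rcpp,
    stats,
    survival,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
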