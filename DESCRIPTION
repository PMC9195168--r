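Package: RelaxoMRR
Title: Low-Field MR Relaxometry Mapping and Hierarchical Classification of
    Brain Hemorrhage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative magnetic-resonance relaxometry (MRR) pipeline for
    identifying blood products in brain parenchyma on low-field scanners.
    Simulates two-hemisphere digital brain phantoms with hemorrhagic lesions
    and variable-TR/variable-TE spin-echo acquisitions, fits voxel-wise
    two-parameter T1 and T2 relaxation models by derivative-free simplex
    minimization, mirrors radiologist-selected suspect voxels into the
    contralateral hemisphere, classifies the pooled voxels by hierarchical
    clustering (Euclidean distance, unweighted-average linkage) with
    silhouette-based model selection, and validates the classification
    against a registered gold-standard lesion contour via confusion counts,
    pooled ROC curves, and trapezoidal and smoothing-spline AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    RNifti,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
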