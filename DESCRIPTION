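Package: octavasc
Title: Quantification of Retinal Microvasculature from OCTA Enface Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying the retinal
    microvasculature on enface optical coherence tomography angiography
    (OCTA) images and relating it to brain imaging markers of cerebral
    small vessel disease. Provides a synthetic enface image generator with
    ground-truth vessel masks, Hessian-based Frangi vessel enhancement,
    dual-threshold (global Otsu plus local adaptive) segmentation, vessel
    density and multifractal branching-complexity metrics with
    skeletonization, an ordinal image-quality and inter-rater agreement
    layer (ICC, Spearman correlation), and covariate-adjusted linear
    association models reporting standardized betas.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    igraph,
    png,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
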