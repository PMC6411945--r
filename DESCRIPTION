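Package: cytoquant
Title: Quantification of Cytoskeletal and Motility Phenotypes in
    Epithelial Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-quantification pipelines for cytoskeletal and motility
    phenotypes of cultured epithelial monolayers: morphometry of EB1
    plus-end comets (ellipse-fit aspect ratio per cell), microtubule
    density scoring by curvilinear ridge detection and re-rendering,
    spot tracking of EB1-GFP comets in time-lapse movies with speed,
    duration and displacement metrics, and kymograph-based quantification
    of lateral cell movement via Feret-angle deviation from the time
    axis.  Shared preprocessing (maximum projection, rolling-ball
    background subtraction, integer upscaling, translational
    stabilization by phase correlation, temporal running average),
    aggregation of manual epithelial/mesenchymal island annotations,
    summary statistics and qPCR delta-delta-Ct fold changes, and a
    synthetic-microscopy generator with serialized ground truth so every
    stage is validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
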