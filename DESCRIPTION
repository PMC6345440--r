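Package: deepstroma
Title: Deep Stroma Scoring of Colorectal Cancer Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating a hazard-ratio-weighted "deep stroma
    score" from nine-class tissue decomposition of hematoxylin-eosin (H&E) colorectal
    cancer histology. Includes Macenko stain normalization, a small trainable
    nine-class tissue-texture classifier with softmax activations, sliding-window
    decomposition of multitissue regions with per-patient max pooling, Youden-index
    optimal cutpoints, univariable and multivariable Cox proportional-hazards
    modelling, and a synthetic-data generator (procedural tissue textures, composite
    regions with ground-truth masks, and survival cohorts with planted
    proportional-hazards effects) so that the whole pipeline is testable end to end
    without external image archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    jsonlite,
    png,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
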