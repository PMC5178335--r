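Package: batvoc
Title: GMM-UBM Classification of Animal Social Vocalizations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for asking how much information animal
    social calls carry about their emitter, addressee, behavioural context
    and interaction outcome. Vocalizations are segmented into voiced
    syllables, represented by 64-dimensional Mel-frequency cepstral
    coefficient frames, and classified with a GMM-UBM likelihood-ratio
    classifier (universal background model plus MAP-adapted per-class
    mixtures), evaluated by leave-one-out cross-validation, balanced
    accuracy and label-permutation tests, with a score-space linear
    discriminant projection for visualization. A seeded synthetic
    vocalization generator with controllable planted effect sizes makes
    every stage testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    S4Vectors,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, Visualization
RoxygenNote: 7.3.3
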