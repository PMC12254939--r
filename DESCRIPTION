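Package: cealux
Title: Dynamic LED Lighting Analytics for Controlled-Environment Agriculture
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models piecewise-constant LED lighting regimes for indoor
    lettuce production and the analyses built on them: daily light integral
    (DLI) arithmetic with equal-DLI scaling and cyclic photoperiod shifting;
    electricity spot-price diurnal profiling and cost scheduling, including
    optimal anchoring of a fixed regime shape against cheap hours; extraction
    of Fv/Fm, NPQ and partially relaxed NPQ from pulse-amplitude-modulated
    chlorophyll-fluorescence quenching traces; top-view RGB canopy
    segmentation with greenness, roundness, compactness and expansion-rate
    phenometrics; and LC-MS feature-table preprocessing (retention-time,
    intensity, QC-RSD and class-presence filters, low-decile imputation,
    log/Z normalization, PCA projection) plus diel carbohydrate-to-DLI
    association. Seeded synthetic-data generators with machine-readable
    ground truth make every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    jsonlite,
    png,
    withr,
    EBImage,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    cluster
biocViews: Software, Phenotyping, Metabolomics, QualityControl, Preprocessing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
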