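Package: forestmon
Title: Forest Disturbance Monitoring from Multispectral Image Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Offline pipeline for satellite-based forest health monitoring:
    builds cloud-free annual composites from Sentinel-2-like multiband scene
    collections (spatial, temporal and cloud-metadata filtering plus QA-bitmask
    masking), computes NDVI and per-pixel standardized Z-NDVI anomalies,
    classifies forest damage by anomaly threshold, validates damage maps against
    compartment-level field reports via confusion matrices, and classifies
    dominant tree species with a random-forest classifier aggregated to
    compartment level by zonal majority. Includes a seeded synthetic-scene
    generator with known ground truth (species phenology, damage events, cloud
    fields) so the whole chain is testable without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    mgcv,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
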