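Package: paleoreef
Title: Deep-Time Habitat Suitability Modelling for Warm-Water Coral Reefs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Presence-background maximum-entropy habitat suitability
    modelling for warm-water coral reefs over geological timescales.
    Provides grid plumbing for bathymetry and climate layers (minimum-depth
    aggregation, bilinear regridding, shallow-water masking, focal gap
    filling, spatial subsampling), a from-scratch L1-regularised maximum
    entropy model with linear and quadratic features and logistic output,
    bootstrap replication, stage-level hindcasting, model evaluation (AUC,
    continuous Boyce index, least-training-presence and MaxSSS binary
    thresholds, multivariate environmental similarity surfaces), fossil
    validation via random-point null models with one-sided Wilcoxon tests,
    and spatiotemporal summaries (area-weighted hemispheric centroids, reef
    zone, binned habitat area). A seeded synthetic-world generator supplies
    bathymetry, climate, modern presences and fossil localities so the full
    pipeline runs and is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
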