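Package: divermap
Title: Multi-Scale Plant-Mycorrhizal Fungal Richness Correlation Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing gridded predictions of vascular plant and
    mycorrhizal (arbuscular and ectomycorrhizal) fungal species richness.
    Builds consensus richness layers from paired prediction rasters, masks
    high-uncertainty cells by percentile thresholds on prediction-spread
    layers and cross-study disagreement, estimates Spearman richness
    correlations from stratified random cell samples at global, biome and
    ecoregion scales, partitions the deviance in fungal richness
    attributable to plant richness with penalized-spline additive models,
    tests whether the sign of zonal correlations tracks the concordance of
    plant and fungal responses to environmental gradients, propagates
    per-cell prediction uncertainty into correlation estimates by Monte
    Carlo, and quantifies the overlap of percentile-defined richness
    hotspots. Includes a seeded synthetic-world generator with known
    ground truth for validation, plain-text (ESRI ASCII grid) raster
    input/output, and an end-to-end reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
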