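Package: worldseasons
Title: Two-Tier Global Seasonal Classification from Monthly Climate Normals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies every land grid cell into one of four climate zones
    (desert, arctic/high-montane, tropical, temperate) by fixed threshold
    rules, then clusters the twelve months of each cell into named seasons
    with zone-specific weighted k-means under a temporal-contiguity
    constraint. Includes circular lag features from monthly temperature,
    precipitation and NDVI normals, a reference-calendar error function with
    a zone-confusion cap, a bounded 9-parameter calibration search with
    elite selection on held-out cities, categorical focal smoothing, Equal
    Earth reprojection, and a synthetic archetype generator for end-to-end
    testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
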