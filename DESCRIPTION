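Package: gzoner
Title: Multi-Criteria Quality, Resilience and Pressure Zoning for Alpine Grasslands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a plot-scale Grassland Quality Index (GQI) from standardized
    vegetation and soil indicators weighted by principal component analysis,
    upscales it to the landscape with UAV multispectral vegetation indices
    (stepwise-AIC regression refined by random-forest permutation importance)
    and to the region with partial least squares regression on NDVI, EVI and
    LAI, estimates ecosystem resilience from a lagged monthly regression of
    LAI on temperature and precipitation, aggregates a grazing-climate
    pressure surface, classifies each criterion by Fisher-Jenks natural
    breaks, and overlays the three classified layers into five adaptive
    management zones. Ships a synthetic-data generator with known ground
    truth so the whole pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
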