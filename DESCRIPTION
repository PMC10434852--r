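Package: optihab
Title: Earth-Observation Proxy Variables and Random-Forest Species
    Distribution Models for Small Mammal Optimal Habitat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping optimal habitat of small mammal species from
    satellite-derived landscape proxy variables and field survey data.
    Implements spectral vegetation and water indices with tasselled-cap
    transforms, temporal percentile metrics over cloud-masked scene
    collections, random-forest land-cover classification with nested focal
    land-cover proportions and terrain derivatives, trapline and transect
    abundance indices via Poisson mixed models with trapping-effort offsets,
    spatial autocorrelation diagnostics (Moran's I, empirical semivariogram),
    all-relevant (Boruta-style) feature selection with shadow features, tuned
    random-forest regression species distribution models validated by
    leave-one-out cross validation, and mean-threshold optimal-habitat
    mapping with area statistics. A synthetic-data module generates
    landscapes, seasonal scene collections and survey observations with
    known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    randomForest,
    ranger,
    rlang,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
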