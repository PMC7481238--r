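Package: landtrax
Title: Trajectory-Based Cropland Conversion Detection, Yield Differentials,
    and Habitat Impact Accounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects cropland expansion and abandonment from annual
    categorical land-cover raster time series using per-pixel trajectory
    encoding, an 8-neighbour majority spatiotemporal filter, five-class
    transition classification with sparse-epoch corroboration, and
    minimum-mapping-unit enforcement with nearest-patch void filling.
    Models representative crop yields with county-level random-forest
    regression and computes national and local (10 km neighbourhood)
    relative yield differentials of newly converted cropland. Quantifies
    habitat consequences of conversion (milkweed stem losses with
    propagated uncertainty, waterfowl breeding-pair accessibility via
    category-midpoint densities, long-term habitat conversion) and
    propagates binary-superclass classification accuracies into per-pixel
    expected conversion accuracy. Includes a seeded synthetic-scene
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
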