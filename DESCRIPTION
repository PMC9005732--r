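Package: afforwet
Title: Afforestation-Wetland Trade-Off Analysis with Budyko Partitioning
    and a Soil-Moisture-Deficit Wetland Diagnostic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how large-scale tree planting reduces runoff,
    soil moisture and wetland extent. Implements the two-parameter Budyko
    water-balance partitioning of precipitation into evapotranspiration and
    runoff with a plant-available-water coefficient per land-cover class, a
    TOPMODEL-style sigmoid diagnostic mapping grid-cell soil-moisture deficit
    to saturated (wetland) fraction with static and dynamic calibration,
    factorial (with/without forest change) attribution, sensitivity
    decomposition of wetland change by aridity zone, near-term planting
    scenario projection with zone-targeted allocation, and basin-level
    aggregation with protection-level statistics. A synthetic-data module
    generates gridded climate, forest trajectories, a bucket soil-moisture
    surrogate, noisy wetland observations, basins and rice masks with known
    ground truth so every stage is testable end to end.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
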