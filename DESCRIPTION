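Package: seafarm
Title: Technoeconomics of Global Seaweed Farming for Climate Benefit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatially explicit technoeconomic analysis of open-ocean seaweed
    farming. From gridded seaweed yields and environmental layers (depth,
    significant wave height, distance to port, 100-year sequestration
    fraction), computes farm-gate production costs per ton dry weight, the
    net cost per ton of CO2 sequestered by sinking harvested biomass to the
    deep sea, and the net cost per ton of CO2-equivalent emissions avoided
    when the harvest displaces food, feed or fuel. Parameter uncertainty is
    propagated by Monte Carlo over uniform ranges; cost-optimal sinking sites
    are located with a land-masked weighted distance transform; parameter
    importance is ranked with gradient-boosted regression trees. Ships a
    synthetic-data generator emulating gridded yield ensembles and ocean
    rasters so the full pipeline runs at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    xgboost,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
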