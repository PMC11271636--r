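Package: shipflow
Title: Gravity-Informed Forecasting of Maritime Shipping Flows and
    Ballast-Water Invasion Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds directed, weighted global shipping networks from port-visit
    trip records, computes the port centrality metrics used as gravity features
    (betweenness, closeness, PageRank, straightness), screens plausible
    origin-destination links on the fully connected network with binary
    classifiers driven by distance and edge-importance features, and forecasts
    ship traffic flows between source ports and destination regions with an
    attention-based gravity model (a small transformer encoder trained with a
    multinomial cross-entropy loss and Common Part of Commuters model
    selection) alongside a deep multilayer-perceptron gravity baseline.
    Predicted flows feed a ballast-water risk stage that weights environmental
    distances between ports by trip intensity. A seeded synthetic-world
    generator produces gravity-law shipping worlds (ports, trips, trade,
    environmental fields) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    igraph,
    jsonlite,
    yaml,
    withr,
    rpart,
    randomForest,
    xgboost,
    caret,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
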