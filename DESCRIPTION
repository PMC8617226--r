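Package: fishres
Title: Social-Ecological Resilience Index for Commercial Fisheries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a hierarchical social-ecological resilience index for
    stock-managed commercial fisheries. Computes ecological indicators
    (distribution area, abundance and mortality trends, thermal traits,
    overexploitation status, recovery time) from stock-assessment time
    series and reference points, and socioeconomic and institutional
    indicators (gear diversity, fleet mobility, catch dependency,
    management investment, co-management, property rights, quota
    compliance) from country fishery records. Indicators are min-max
    normalized with direction reversal, pruned for redundancy by a
    correlation threshold, and averaged stepwise into factor, dimension
    and overall resilience scores per stock and per country-species.
    Includes permutation-importance and latitude-smooth analyses of the
    resulting scores, and a synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    randomForest,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
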