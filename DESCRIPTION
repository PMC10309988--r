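Package: acarecon
Title: Farm-System Economics of Cattle Tick Control and Acaricide Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A farm-system pipeline for evaluating the economics of cattle-tick
    control on smallholder dairy farms. Implements annual cost accounting with
    variable and fixed cost ledgers under two veterinary-service scenarios,
    milk production cost per litre, straight-line depreciation, opportunity-cost
    family labour and a capped mortality cost; classification of larval packet
    test bioassays into four acaricide-resistance levels and binary farm flags;
    farm typology by k-means on ordinally recoded management variables with
    elbow selection; Fisher exact contingency analysis of resistance against
    high tick infestation; and CART regression and classification trees for
    acaricide-treatment cost shares with a repeated train/test split selection
    procedure based on concordance screening, Bland-Altman agreement and
    minimum test error. A seeded synthetic cohort generator reproduces the
    statistical structure of a 105-farm survey so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
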