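Package: ofmscreen
Title: Fluctuation Analysis and Screen Statistics for Originless Chromosome Fragment Maintenance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for studying the maintenance of budding-yeast
    chromosome III derivatives lacking efficient replication origins. Estimates
    per-division chromosome loss rates from parallel-culture fluctuation assays
    (P0, Lea-Coulson median and Luria-Delbruck maximum-likelihood estimators),
    computes the Ofm (originless fragment maintenance) index that contrasts
    destabilisation of origin-depleted and origin-replete derivatives, simulates
    red-sector formation in colonies to reproduce the semi-quantitative
    sectoring screen, and provides a stochastic replication simulator with
    origin competence, firing-time dispersion, finite fork speed, per-kb fork
    failure and dormant-origin rescue. A synthetic-data generator builds
    complete virtual screens so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
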