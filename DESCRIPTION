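Package: microdar
Title: Diversity-Abundance Scaling and Richness Estimation for Microbial Census Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing microbial richness at large scales from
    sample-by-taxon count tables. Implements incidence-based nonparametric
    richness estimators (bias-corrected Chao2, ICE), a spatially explicit
    community simulator for probing estimator bias under uneven abundances
    and aggregated spatial distributions, per-sample species-abundance
    summaries (richness, dominance, evenness, rarity), bootstrapped
    stratified log-log diversity-abundance scaling fits with prediction
    intervals, and a two-input lognormal model that predicts total richness
    from total abundance N and maximum abundance Nmax. Includes a synthetic
    corpus generator with known ground-truth scaling structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    biomformat
Config/testthat/edition: 3
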