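Package: trophinet
Title: Trophic Integration of Non-Native Plants into Microherbivore
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how non-native plants become trophically
    integrated into networks of microherbivores (leaf miners, gall
    formers, borers, mites and plant-pathogenic fungi). Builds per-plant
    microherbivory richness from interaction edge lists, engineers
    macroecological covariates (area of occupancy from gridded
    occurrences, earliest introduction year, native-range centroid
    distance, relatedness to the native flora, woodiness with
    genus-level gap filling), fits hierarchical linear mixed models with
    marginal, conditional and semi-partial R2 decompositions, derives
    integration thresholds by inverting fitted richness-covariate
    relationships, and classifies microherbivore host specialisation
    (mono-, oligo-, meso-, polyphagy). Includes a synthetic bipartite
    network generator with known ground truth for end-to-end testing
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    geosphere,
    lmerTest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
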