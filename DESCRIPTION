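Package: tfehydro
Title: Biomass and Eco-Hydrological Stabilization Analysis for
    Throughfall-Exclusion Drought Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for long-term throughfall-exclusion (TFE)
    drought experiments in tropical forest: quarterly dendrometer census
    processing with per-tree outlier filtering, a site allometric chain with
    wood-density uncertainty propagation, soil-moisture profile integration
    to total column water and biomass-relative water availability, sap-flow
    baseline correction by 10% quantile regression with daily transpiration
    statistics, leaf and wood water-status metrics including a linear
    temperature correction of stem water content, linear mixed-model
    treatment comparisons, and basin-scale biome contextualization. Includes
    a calibrated synthetic two-plot scenario generator with known ground
    truth so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
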