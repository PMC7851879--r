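Package: iptflux
Title: Isotope-Pairing Rate Inference for Benthic and Holobiont Nitrogen Cycling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers nitrogen transformation rates from 15N stable-isotope
    tracer incubations of sediment cores and filter-feeder (holobiont)
    microcosms. Computes net solute and oxygen fluxes from incubation time
    series, partitions denitrification with the isotope pairing technique
    (IPT) from 29N2/30N2 production, estimates dissimilatory nitrate
    reduction to ammonium (DNRA) from 15NH4+ production, anammox from the
    15NH4+ treatment, and N2 fixation from 15N2 incorporation into tissue.
    Includes exact small-sample rank tests for treatment comparisons,
    biomass-to-areal upscaling into a nitrogen budget, and a forward
    simulator of tracer incubations so every inference stage can be
    validated against known ground truth.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
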