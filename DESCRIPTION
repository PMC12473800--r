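Package: sedrisk
Title: Contamination Indices and Ecological and Human Health Risk
    Assessment for River Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes sediment heavy-metal contamination indices
    (contamination factor, geoaccumulation index, enrichment factor,
    pollution load index, modified contamination degree), the Hakanson
    potential ecological risk index with toxic response factors, a
    rank-based site ranking index, and EPA-style human health risk
    estimates (chronic daily doses by ingestion, inhalation and dermal
    contact; hazard quotients and hazard index; carcinogenic risk and
    total carcinogenic risk) for child and adult receptors. Ships
    editable reference tables (geochemical backgrounds, toxic response
    factors, exposure profiles, dose-response constants), a seedable
    lognormal synthetic-sample generator for two-zone river designs, an
    exact Wilcoxon rank-sum zone comparison, and an end-to-end reporting
    pipeline with ggplot2 visualisations and broom-style tidiers.
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
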