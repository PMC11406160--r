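Package: bitenet
Title: Temperature-Driven Bite-Force Feasibility Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Propagates warming-induced body-size change through allometric
    bite-force scaling to build temperature-specific bipartite
    consumer-resource feasibility networks, and quantifies the resulting
    trophic-niche contraction. Provides power-law trait scaling, a
    multiplicative temperature-size rule, Q10 thermal performance with a
    high-temperature plateau, mechanical feasibility networks (an
    interaction is possible when bite force meets the resource's required
    cutting force), node and network metrics (degree, generality,
    connectance), robustness to secondary extinctions via attack-tolerance
    curves, interlayer link turnover across temperature layers, a synthetic
    community generator, and an end-to-end temperature-sweep pipeline with
    hypothesis evaluation and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
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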