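Package: telosas
Title: Survivor-Associated Senescence and Telomere Dynamics in
    Telomerase-Negative Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of survivor-associated senescence (SAS) in
    telomerase-negative budding yeast maintaining telomeres by
    homology-directed repair. Turns daily OD600 records into population
    doublings and replicative-potential curves, implements the SAS-rate
    local-minimum statistic (pairwise smoothing, neighborhood-window minima,
    PD counting), estimates telomere shortening rates in bp per population
    doubling by difference quotients and linear regression, quantifies gel
    densitometry lane profiles into relative telomere lengths, and provides
    delta-Ct TERRA quantification and ChIP-qPCR percent-input normalization.
    A stochastic simulator of clonal telomere/TERRA/growth dynamics generates
    every input table, so the whole pipeline is testable without
    experimental data.
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
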