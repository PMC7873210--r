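Package: icofit
Title: Equilibrium Assembly Analysis of Two-Component Icosahedral Protein Nanomaterials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the in vitro assembly of two-component
    icosahedral protein nanomaterials (I53-class designs built from 20 trimeric
    and 12 pentameric building blocks). Implements a multi-component mass-action
    equilibrium model in numerically safe log space, contact free-energy fitting
    by root mean squared percent error minimization against normalized size
    exclusion chromatography peak areas, Hill cooperativity analysis, chevron
    summaries, empirical melting and aggregation temperature callers, and a
    seeded synthetic-data generator emulating the replicate structure of SEC and
    thermal melt experiments.
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
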