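Package: epiwalk
Title: Epistasis Along Adaptive Walks on Simulated Fitness Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for studying how the prevalence of sign,
    synergistic, and antagonistic epistasis changes along adaptive walks.
    Generates NK and Rough Mount Fuji fitness landscapes with tunable
    ruggedness, simulates strong-selection-weak-mutation and equal-weight
    adaptive walks from low-fitness starting genotypes, classifies genotype
    quadruples by the fitness rank of the off-path genotype, samples
    quadruples stratified by fitness quartile, and aggregates epistasis
    frequencies by walk step and by quartile together with
    percentile-interval summaries that expose the regression-to-the-mean
    mechanism behind the changing epistasis pattern.
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
    igraph,
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
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
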