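Package: breedsim
Title: Formalize and Stochastically Optimize Stage-Gate Plant Breeding Schemes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to formalize a plant breeding pipeline as a machine-readable
    breeding scheme (market segments, product profiles, and stage-wise crossing,
    evaluation and selection decisions), compute derived program metrics, and
    export flowcharts. Includes a forward-in-time quantitative-genetics
    simulator: Wright-Fisher burn-in founders on a multi-chromosome genome,
    Poisson-crossover meiosis, an additive trait with Finlay-Wilkinson
    genotype-by-environment interaction, stage-calibrated phenotyping, and a
    stage-gate breeding engine with overlapping cohorts and parent-recycling
    policies. A treatment-grid layer enumerates resource-allocation
    alternatives (numbers of parents, crosses and progeny at fixed program
    size) and summarizes genetic gain across replicated simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tibble,
    dplyr,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    knitr
Config/testthat/edition: 3
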