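Package: latticepop
Title: Discrete-Generation Metapopulation Simulation on a Cell Lattice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates communities of digital species on a one-dimensional
    lattice of resource-limited cells across discrete, non-overlapping
    generations.  Species reproduce through direct and indirect (partner-
    conferred) offspring, interact pairwise within cells (predation, brood
    parasitism, resource feeding, mutual inhibition), compete for a fixed
    number of resource units per cell, and disperse their offspring under
    local-neighbourhood, global-aggregated, or gregarious strategies.
    Includes a Chebyshev bound on the exclusion probability implied by the
    variance of a spatial distribution, scenario generators for classic
    questions (aggregation inefficiency, predator-prey stabilisation,
    breakdown of competitive exclusion and the paradox of the plankton),
    and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
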