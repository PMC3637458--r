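Package: rankedcoal
Title: Ranked Gene Tree Probabilities Under the Multispecies Coalescent
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Polynomial-time computation of the probability of a ranked gene
    tree topology given a species tree with divergence times under the
    multispecies coalescent, by dynamic programming over the species-tree
    intervals with hypoexponential waiting-time distributions. Includes
    unranked gene tree probabilities by summation over rankings, the Minimize
    Ancient Coalescence (MAC) and Minimize Deep Coalescence (MDC) parsimony
    criteria, maximum-likelihood inference of a ranked species tree (with
    internal branch lengths) from collections of ranked gene tree topologies,
    and an exact multispecies-coalescent simulator of ranked gene trees.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
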