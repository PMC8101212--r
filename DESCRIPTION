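Package: msatpop
Title: Microsatellite Population Genetics and Coalescent-Based Demographic Inference
Version: 0.9.0
Authors@R:
    person("msatpop", "developers", email = "msatpop@example.org", role = c("aut", "cre"))
Description: Tools for diploid microsatellite genotype data: input/output
    (delimited tables, GenePop), allele frequencies and diversity statistics,
    rarefied allelic richness, Weir-Cockerham F-statistics, Hardy-Weinberg and
    linkage-disequilibrium permutation tests, Brookfield null-allele estimation,
    Ohta's variance decomposition of linkage disequilibrium in subdivided
    populations, LD-based effective population size, population distances
    (Cavalli-Sforza and Edwards chord distance, pairwise FST), neighbour-joining
    trees, hierarchical AMOVA, Mantel tests of isolation by distance,
    maximum-likelihood mixture clustering with information-criterion model
    selection, hybrid and backcross classification, DAPC and factorial
    correspondence ordinations. Includes a multi-population coalescent
    simulator for microsatellites under a generalised stepwise mutation model
    with single-nucleotide indels, Approximate Bayesian Computation for
    demographic model choice and parameter estimation, and generators of
    labelled synthetic datasets with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    optparse,
    vegan,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
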