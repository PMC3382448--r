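Package: deepcoal
Title: Minimum Deep Coalescence Species Trees and Consensus Properties
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Species-tree inference from rooted binary gene trees under the
    minimum deep coalescence (MDC) criterion. Provides the deep coalescence
    cost and its extra-lineage normalisation, LCA mappings, strict consensus
    trees and the Pareto property on clusters, a repair algorithm based on the
    shallowest regrouping edit that augments any candidate species tree with
    all consensus clusters while strictly lowering its aggregated cost, an
    exact solver by exhaustive topology enumeration, a rooted-SPR
    hill-climbing heuristic, a divide-and-conquer search that independently
    refines each multifurcation of the strict consensus, and simulators for
    grafted gene-tree profiles, random binary refinements of complete b-ary
    consensus skeletons, and multispecies-coalescent gene trees on Yule
    species trees.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
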