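Package: stomevol
Title: Comparative Phylogenetic Analysis of Stomatal and Genome Size Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether habitat shapes stomatal (guard-cell)
    size independently of genome size in woody plant clades. Implements
    phylogenetic generalized least squares with simultaneous maximum
    likelihood estimation of Pagel's lambda, phylogenetic signal statistics
    (Blomberg's K with a permutation test, Pagel's lambda with a likelihood
    ratio test), maximum likelihood ancestral state estimation for
    continuous traits, maximum likelihood estimation of nested variance
    components (genus / species-within-genus / replicate), a genus-level
    bootstrap randomization test comparing within-genus variance ratios
    between two traits, and flow-cytometry genome size estimation from
    peak means against an internal reference standard. A synthetic-data
    generator produces dated trees and hierarchical trait tables with the
    statistical structure the analyses assume, and a pipeline layer
    orchestrates the high-level (among-genus) and low-level (within-genus)
    analyses end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape (>= 5.0),
    phytools,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    nlme,
    optparse
Config/testthat/edition: 3
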