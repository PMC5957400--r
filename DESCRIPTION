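Package: geneshop
Title: Gene Shopping for Divergence-Time Estimation in Phylogenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Winnow phylogenomic gene sets to genes suitable for molecular
    dating. For every rooted gene tree the package scores clock-likeness
    (root-to-tip path-length variance), topological concordance with a focal
    species tree (bipartition comparison), and information content (total
    tree length), then ranks and selects genes by these criteria. A
    Felsenstein-pruning likelihood engine provides the standard strict-clock
    likelihood-ratio test and maximum-likelihood strict-clock dating on a
    fixed topology. Simulators for Yule chronograms, branch-rate models
    (strict clock, noisy clock, uncorrelated lognormal) and sequence
    evolution support validation experiments: clock-test false-rejection
    rates, rate-heterogeneity landscapes, and shopped-versus-random gene
    dating comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
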