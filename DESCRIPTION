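Package: treeassoc
Title: Genealogy-Based Association Fine-Mapping with Fuzzy P-Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fine-maps disease-predisposing variants from phased case/control
    haplotypes by sampling marginal ancestral trees, mutation rates and
    recombination rates at genomic focal points with Markov chain Monte Carlo,
    scoring each sampled tree with a bipartition maximum-correlation
    association statistic, and expressing the evidence as a fuzzy p-value
    against the neutral-coalescent prior. Includes a coalescent simulator for
    the prior null, a synthetic case/control panel generator with a planted
    causal variant, single-SNP Fisher exact comparators, and region-level
    orchestration across a grid of focal points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
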