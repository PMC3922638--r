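Package: clonetree
Title: Bayesian Inference of Tumor Subclonal Lineage Trees from SNV Read Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the phylogeny, genotypes, and population frequencies of the
    major subclonal lineages of a tumor from deep-sequencing allele counts of
    somatic single nucleotide variants (SNVs), in one or more samples of the
    same tumor. The model places a tree-structured stick-breaking process prior
    over lineage trees, marginalizes variant-population genotypes under a
    Dirichlet prior in a binomial read-count likelihood, and enforces the
    infinite-sites constraint (a parent lineage's frequency is at least the sum
    of its children's) through auxiliary simplex weights updated by
    Metropolis-Hastings. Includes the sum-rule and crossing-rule topology
    classifiers, a brute-force consistent-tree enumerator, posterior consensus
    summaries (co-clustering, correlation clustering, partial-order plots as
    DOT), and a read-count simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
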