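Package: hybridhallmarks
Title: Population-Genetic Diagnostics for Hybrid Speciation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether a putative hybrid species carries the
    genomic hallmarks of an old, admixture-founded lineage rather than a
    contemporary hybrid swarm. Implements locus-by-locus AMOVA fixation
    indices (Phi-ST) with permutation tests for aligned sequence loci and
    dominant binary (AFLP-style) markers, ancestry-informative marker
    selection and four-way classification, a Gibbs-sampler admixture model
    for dominant markers, pairwise exact tests of linkage disequilibrium
    with population-level summaries, species-specific polymorphism and
    haplotype statistics with one-way ANOVA comparisons, neighbor-joining
    phylogenies with bootstrap support and Fitch parsimony trait mapping,
    a mutation-rate split-time calibration, and a structured-coalescent
    simulator of hybrid-speciation demographies (maternal and Z-linked
    inheritance, dominant markers, laboratory crosses, recent hybrid
    swarms) so that every diagnostic can be validated on data with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
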