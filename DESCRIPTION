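Package: pedimpute
Title: Pedigree-Based Phasing and Imputation in Founder Populations via IBD Cliques
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Long-range phasing and sequence-variant imputation for founder
    populations with deep pedigrees. Framework genotypes are phased by
    Mendelian rules, sibling templates and surrogate relatives; identity by
    descent (IBD) between every pair of haplotypes is detected with a
    two-state hidden Markov model; IBD segments are indexed into per-marker
    cliques that support constant-time IBD queries; sequence variants typed
    in a small sequenced subset are propagated through the cliques with a
    queue-and-majority-vote algorithm; parental origin of quasi-founder
    haplotypes is assigned from clique kinship separation; and sequence
    genotypes are quality controlled with a generalized Mendelian check
    based on IBD2 discordance. A gene-dropping simulator provides ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    igraph,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    vcfR,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
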