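Package: polycoal
Title: Polyploid Subgenome Assignment and Reticulate Network Inference by
    Deep-Coalescence Minimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis workflow for inferring the hybrid origins of
    auto- and allopolyploid plants from multi-locus amplicon data.  Calls
    alleles per sample and locus from amplicon reads with ploidy-aware
    cluster retention, PCR-chimera removal and IUPAC consensus building;
    assigns the alleles of polyploids to diploid subgenomes by minimizing
    deep coalescence over posterior samples of gene trees (hill climbing
    with reinitialization and a gene-tree-probability tie-break under the
    multispecies coalescent); folds the resulting multi-labeled species
    tree into a reticulate species network with merged node-age intervals;
    ranks species-delimitation scenarios for the polyploids; and builds
    statistical-parsimony (TCS) haplotype networks from plastid sequences.
    A coalescent simulator of planted polyploid histories generates fully
    labeled synthetic data sets so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    igraph,
    Rcpp,
    Biostrings,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
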