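Package: gwasoverlap
Title: Multi-Level Functional Overlap of Disease-Associated Variants Across Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how much genome-wide association signal is shared
    between populations at five levels of biological granularity: tagSNPs,
    linkage-disequilibrium-expanded loci, genes, enriched biological
    functions, and locus-constrained coherent subnetworks. Provides Jaccard
    overlap matrices and cumulative overlap functions at every level,
    level-matched permutation significance tests (z-scores and empirical
    p-values), hierarchical clustering of populations, subtype
    stratification, and a synthetic multi-population study generator with
    tunable SNP-level versus pathway-level sharing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
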