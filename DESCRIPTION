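Package: regulonTracer
Title: Comparative Phylogenetic Profiling of the Crl Regulon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for tracing a curated transcriptional regulon across
    bacterial and archaeal genomes. Provides a validated data model and
    summary statistics for the Crl regulon of Escherichia coli K-12
    (signed regulator-gene edges, transcription units, evidence codes,
    hypergeometric functional enrichment), an exact Smith-Waterman /
    Needleman-Wunsch affine-gap alignment core with Karlin-Altschul
    E-values at a fixed database size, bidirectional-best-hit ortholog
    assignment, per-division phylogenetic profiles with hierarchical
    clustering under uncentered-correlation or Pearson distances, a
    Tamura-Nei (TN93) distance / neighbor-joining / bootstrap phylogeny
    stack with a pruning likelihood, and a deterministic synthetic
    proteome generator with planted ortholog truth sets for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
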