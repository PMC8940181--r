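Package: tcrgwas
Title: Genome-Wide Association Analysis of T-Cell Receptor Repertoire Features
Version: 0.1.0
Authors@R:
    person("Repertoire", "Genomics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links SNP genotypes to V(D)J recombination statistics of T-cell
    receptor (TCR) repertoires. Provides parsimonious V(D)J recombination
    scenario annotation of TCR reads (nucleotide trimming, N-insertions,
    P-nucleotides, productivity), condensation of annotated repertoires into
    per-subject and per-gene-allele-group feature tables, simple and
    gene-conditioned fixed-effects association models with clustered-bootstrap
    p-values, conditional scans for independent signals, genotype PCA with
    ancestry-cluster statistics, genomic inflation diagnostics, Bonferroni
    threshold bookkeeping, and a synthetic cohort generator with planted
    effects so that the whole pipeline is testable end to end without access
    to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    S4Vectors,
    SummarizedExperiment,
    GenomicRanges,
    optparse
Config/testthat/edition: 3
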