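Package: sweepscan
Title: Selection-Signature Scans with FLK and hapFLK in Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome scans for positive selection across hierarchically
    structured populations. Implements genotype quality control with an
    exact Hardy-Weinberg test, Storey q-values, a VanRaden genomic
    relationship matrix and mixture-model relatedness filtering; Reynolds
    distances, neighbour-joining population trees and the drift kinship
    matrix F; the FLK single-SNP differentiation test and the hapFLK
    haplotype-cluster extension with EM fitting of the Scheet-Stephens
    model and empirical chi-squared recalibration; construction and gene
    annotation of selection-signature regions; quantification of allelic
    heterogeneity through an eigen-decomposition-based SNP correlation
    matrix and a posterior on the number of independent selected variants;
    and a synthetic-data generator (drift on a tree, sweeps, mosaic
    haplotypes, related-pair spikes) with full truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    mclust,
    pracma,
    MASS,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
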