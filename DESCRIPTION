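Package: tehet
Title: Transposable-Element Proximity, Heterozygosity and Selection Scans
    Across an Inbreeding Gradient
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for testing whether proximity to
    transposable elements (TEs) shapes genome-wide heterozygosity and
    signatures of selection across populations spanning an inbreeding
    gradient. Annotates biallelic SNPs with the distance, orientation and
    superfamily of their nearest TE; computes per-sample inbreeding
    coefficients, per-locus minor allele frequencies and Weir-Cockerham
    F_ST; runs two complementary genome scans (a PCA-Mahalanobis outlier
    scan and a Bayesian F_ST decomposition into locus-specific alpha and
    population-specific beta effects fitted by reversible-jump MCMC);
    discriminates balancing from purifying selection using allele
    frequencies and 0-fold/4-fold codon annotation; fits a ladder of
    binomial complementary log-log regressions for the probability that a
    locus is heterozygous, deriving a data-driven "TE Effect" grouping of
    superfamilies; and compares per-superfamily outlier proportions across
    evolutionary lineages, with gene-ontology enrichment and
    gene-essentiality analysis of variance. A synthetic-data module
    generates genotype, TE-annotation and gene-annotation fixtures with
    planted ground truth so that every stage can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    car,
    glmmTMB,
    vcfR,
    rtracklayer,
    BiocGenerics,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
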