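Package: cryptline
Title: Discovery and Characterization of Cryptic Sympatric Lineages in
    Highly Selfing Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying and characterizing cryptic sympatric
    lineages of highly selfing annual plants from SNP genotype matrices and
    leaf morphometrics. Implements reduced-representation (RAD/GBS) genotype
    quality filtering, descriptive population genetics (observed and unbiased
    expected heterozygosity, inbreeding coefficients, rarefied allelic
    richness, private alleles, Nei's standard genetic distance, Weir-Cockerham
    F_ST, genotype PCA), forward simulation of F1/F2/F3 hybrids by crossing
    and selfing with maximum-likelihood hybrid-index estimation and empirical
    classification, per-locus F_ST divergence-island scans, selection of
    lineage-diagnostic SNP panels with assay-suitability rules and sample
    assignment, and elliptic Fourier analysis of leaf outlines with trait
    ANOVA and cross-validated linear discriminant analysis. A synthetic-data
    module generates genotype matrices, RAD-locus sequences, leaf outlines and
    trait tables with realistic lineage structure so the whole pipeline runs
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    graphics,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
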