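Package: panelscan
Title: Diversity, Divergence and Relatedness Scans for Inbred SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Characterization of structured inbred breeding panels genotyped
    on biallelic SNP arrays. Provides genotype input/output for a HapMap-style
    text dialect and a plain dosage table, per-locus quality control (missing
    rate, heterozygosity, minor allele frequency) with two-tier filtering,
    gene-diversity and polymorphism-information-content estimators with
    group-wise summaries and binned genome scans for diversity hotspots,
    between-group allele-frequency divergence analysis (private-allele
    screening, chi-square tests, binned variant-SNP ratios), linkage
    disequilibrium decay estimation from dosage correlations, pairwise
    identity-by-state similarity with conserved-segment detection, the
    VanRaden genomic relationship matrix, Nei genetic distances with
    neighbor-joining trees, Evanno delta-K post-processing of admixture
    log-likelihoods, and a synthetic structured-panel generator with a truth
    manifest so every stage can be validated against known parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
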