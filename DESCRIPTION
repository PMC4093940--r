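Package: mirsnp
Title: Allele-Aware MicroRNA Target-Site Analysis of Trait-Associated SNPs
Version: 0.1.0
Authors@R: person("BASE", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline linking quantitative-trait GWAS
    signals to microRNA-mediated regulation: an additive-model linear
    association scan with covariate and principal-component adjustment,
    linkage-disequilibrium proxy search, allele-aware prediction of canonical
    miRNA seed sites in 3'UTRs with a k-of-n scorer consensus, permutation
    enrichment of associated SNPs in miRNA target genes, eQTL regression with
    interquartile-range outlier filtering, and luciferase reporter-assay
    statistics. A synthetic-data module generates genotype, phenotype,
    targetome, expression and reporter-plate inputs with known ground truth
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
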