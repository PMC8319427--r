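Package: herdscan
Title: Host Genetic Effects on Gut Microbiota in Multibreed Herds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying host genetic effects on the gut microbiota
    of multibreed livestock populations. Implements genotype quality control
    (call rate, minor allele frequency, Hardy-Weinberg, heterozygosity and
    identity-by-state outliers), community diversity and ordination (Shannon
    index, Bray-Curtis dissimilarity, principal coordinates, PERMANOVA),
    genomic (VanRaden) and microbial relationship matrices, a single-component
    REML animal model for taxon heritability and phenotype microbiability,
    two-step mixed-model genome scans with genomic control and
    Benjamini-Hochberg FDR, regression-based breed-composition and phenotype
    association scans, Spearman co-occurrence networks with hub detection,
    and a synthetic multibreed herd generator that plants known heritabilities
    and microbiabilities so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
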