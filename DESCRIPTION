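Package: selfingclock
Title: Dating Obligate Selfing from Multilocus Genotype Uniformity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dating the origin of obligately self-fertilising
    (completely cleistogamous) plant lineages from the persistence of
    identical multilocus microsatellite genotypes. Provides the analytic
    genotype-uniformity clock for SSR markers under obligate selfing, a
    forward-time Monte-Carlo simulator of microsatellite mutation
    accumulation in selfing lines, SSR summary statistics (allelic
    richness by rarefaction, heterozygosities, inbreeding coefficients,
    private alleles, Nei's D_A distance and neighbour-joining trees with
    locus bootstrap), SNP-matrix filtering and polarisation with
    fixed-difference and nucleotide-diversity summaries and the Evanno
    Delta-K statistic, per-sample heterozygous-SNV "genomic selfing
    syndrome" metrics with sister-pair t-tests, phylogenetic generalized
    least squares under Brownian motion, and a synthetic-data generator
    that emulates the sampling design of a sister-pair study of
    mixed-mating and obligately selfing orchids.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
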