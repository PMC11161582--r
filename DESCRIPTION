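Package: pangotrace
Title: Population Genetics and Trade Tracing for Microsatellite and
    Mitochondrial Data from Trafficked Wildlife
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing population genetic diversity and tracing
    the geographic origin of traded animals from co-dominant microsatellite
    genotypes and mitochondrial sequence data, developed around the
    white-bellied pangolin bushmeat trade in western Central Africa.
    Implements GenAlEx-format genotype IO, per-population diversity
    statistics (Na, Ho, He, uHe, rarefied allelic richness), Weir-Cockerham
    F_IS and pairwise F_ST with permutation tests, Hardy-Weinberg, linkage
    and null-allele diagnostics, Mantel isolation-by-distance on
    Cavalli-Sforza-Edwards chord distances, forensic identity indices (PI,
    uPI, PIsibs, psex) and genotype matching, generalized private-allele
    rarefaction with locus selection and market/seizure source assignment,
    a coalescent heterozygosity-excess bottleneck test under SMM/TPM
    mutation models, and a cytochrome-b workflow (haplotype collapsing,
    diversity, K2P/NJ lineage assignment, mismatch-distribution expansion
    tests). A synthetic-data generator reproduces the statistical structure
    of reference populations, market mixtures, duplicates and missingness
    so that every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    geosphere,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
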