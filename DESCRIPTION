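Package: svpopgen
Title: Population Genomics of Structural Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genomic analysis of structural variant (SV)
    call sets in multi-population diploid cohorts. Implements diversity
    statistics (per-site and windowed nucleotide diversity, heterozygosity,
    linkage-disequilibrium decay), Weir-Cockerham F_ST with permutation
    P-values, a derived-allele differentiation index with ancestral
    polarization, the population branch statistic, breakpoint-density hotspot
    detection, telomere enrichment, reciprocal-overlap interval matching
    (novelty, QTL and ATAC-peak comparisons), genic-region SV annotation,
    cross-species convergent-gene permutation tests, allele-frequency based
    introgression scans, and association post-processing including a
    variance-explained formula computed from GWAS summary statistics. Ships a
    Balding-Nichols based synthetic cohort simulator with planted selection,
    introgression and hotspot signals plus ground-truth records so every
    stage can be exercised end to end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
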