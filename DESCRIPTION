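Package: sweepscan
Title: Two-Population Selection-Signature Scans for SNP Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for detecting selective sweeps between two
    populations from phased biallelic SNP genotypes. Implements variant
    filtering, principal-component analysis and linkage-disequilibrium
    decay summaries, the cross-population extended haplotype homozygosity
    (XP-EHH) scan with genome-wide normalization and two-sided normal
    p-values, calling of potentially selected regions (PSRs) by outlier
    merging and flank extension, eigenvector-phenotype association scans
    with genomic control (EigenGWAS), expedited mixed-model association
    (kinship + one-shot REML + per-marker generalized least squares),
    interval annotation of PSRs against gene and QTL tables with
    hypergeometric term enrichment, and a seed-deterministic
    two-population simulator (Balding-Nichols divergence, founder-copying
    haplotypes, optional hard sweep) for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    jsonlite,
    IRanges,
    S4Vectors,
    GenomicRanges
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
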