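Package: lactovar
Title: Milk Protein Variant Discovery from Multi-Sample Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies bovine milk-protein variants from multi-sample DNA
    sequence data for the six major milk protein genes (CSN1S1, CSN2, CSN1S2,
    CSN3, LALBA, PAEP). Reads and quality-filters gene-region variants from
    VCF, classifies them by genomic region, estimates coding-haplotype
    frequencies by expectation-maximization from unphased genotypes, translates
    haplotypes into mature-protein substitution sets, matches them against a
    known-variant catalog, names novel variants with a hierarchical dotted
    nomenclature, and reports per-breed variant frequencies and
    single-substitution variant networks. Includes a multi-breed diploid
    population simulator with a ground-truth ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
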