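Package: kirpop
Title: Population Analysis of KIR Gene-Content Haplotypes and Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for population-level analysis of the killer-cell
    immunoglobulin-like receptor (KIR) gene complex from copy-number and
    allele-level genotype data. Decomposes per-individual KIR gene copy-number
    profiles into pairs of gene-content haplotypes, discovers candidate novel
    deletion and duplication haplotypes, estimates allelic haplotype
    frequencies by an expectation-maximization (gene-counting) algorithm,
    computes multi-allelic pairwise linkage disequilibrium (D, D', r squared)
    with permutation p-values, and classifies observed allele variable-site
    vectors as known, recombinant, or novel single-nucleotide variants with
    exon, codon, and Grantham-distance annotation. Includes a configurable
    synthetic cohort generator with truth labels so every analysis stage can
    be validated without access to protected genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
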