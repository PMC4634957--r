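Package: exomeAR
Title: Recessive Disease-Gene Discovery from Exome Variant Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for mapping autosomal-recessive disease genes
    from small exome-sequenced cohorts. Filters variant calls to functional
    (non-synonymous and splice-site) changes, excludes catalogued
    polymorphisms, nominates candidate genes from pedigree structure
    (shared homozygosity in offspring of consanguineous unions, trans
    compound heterozygosity in affected sib pairs, exclusion by unaffected
    relatives), verifies co-segregation, derives protein-level consequences
    of splice-site mutations (exon skipping, intron retention) with
    HGVS-style frameshift naming, and computes cohort genotype, allele-count
    and clinical-feature statistics with exact and summary-based tests. A
    seeded synthetic-cohort generator with truth files makes every stage
    testable without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
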