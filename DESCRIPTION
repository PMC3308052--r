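Package: panelseeker
Title: Targeted Gene-Panel Capture Design and Rare-Variant Analysis for
    Mendelian Hearing Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing targeted capture gene panels (centered bait
    tiling with repeat-overlap budgets), assessing capture performance,
    calling zygosity from per-site read counts, detecting cryptic indels that
    present as adjacent weakly supported substitutions, filtering variants
    down to rare conserved candidates (dbSNP clinical-flag, conservation,
    cohort-recurrence and 1000 Genomes filters with codon-level effect
    classification), testing co-segregation of candidate alleles in
    pedigrees under recessive or dominant models, and computing founder
    allele statistics (allele/carrier frequencies, exact case-control
    comparison, attributable fraction). Includes a synthetic-data generator
    emulating a multi-gene deafness panel so the whole pipeline is testable
    without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
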