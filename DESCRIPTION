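Package: hapasm
Title: Discovery of Haplotype-Dependent Allele-Specific Methylation from
    Small WGBS Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects regions of common inter-individual DNA methylation
    differences (DMRs) from small cohorts of whole-genome bisulfite
    sequencing methylomes using a synthetic extreme-methylome strategy,
    assigns empirical significance via a pooled-rate binomial null,
    models the Hardy-Weinberg detection rate of allele-specific
    epialleles, classifies per-sample DMR methylation into epigenotypes
    with a three-component beta mixture, scores SNP-DMR co-variation as
    a product of posteriors, and characterises DMRs by flanking
    methylation and annotation enrichment against matched random
    regions. Ships a read-level cohort simulator with planted
    allele-specific DMRs so the full pipeline is testable without
    restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
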