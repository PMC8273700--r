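Package: exprvar
Title: Reliable SNP Detection and Genotype Calling from RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for population-scale SNP detection and
    genotype calling from bulk RNA-seq call sets: site-level hard filters
    (quality-by-depth, phred-scaled Fisher strand bias), genotype call-rate
    metrics conditioned on per-genotype read depth, RNA-vs-DNA detection and
    genotype concordance evaluation, multi-tissue genotype merging, sequence
    and annotation context flags (SNP clusters, homopolymers, splice-junction
    proximity, genomic feature classes), an exon expression threshold derived
    from shuffled background loci, allele-specific expression calling from
    phased haplotype read counts (exact binomial test with per-sample
    Benjamini-Hochberg correction), and cross-population accounting with
    identity-by-state clustering. Ships a synthetic-data generator that
    emulates expression-dependent coverage so every stage is testable without
    any sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    Biostrings,
    IRanges,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
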