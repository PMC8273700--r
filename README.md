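# exprvar — reliable SNP detection and genotype calling from RNA-seq

RNA-seq read depth follows gene expression: a SNP in a highly expressed
exon is covered by hundreds of reads while one in a silent gene gets none,
and introns of immature transcripts sit in between. Pooling reads across a
population therefore *detects* many SNPs whose per-individual depth is far
too low to *genotype*. `exprvar` is an R package for researchers who want
to mine population-scale RNA-seq cohorts for variants anyway — typically in
species where whole-genome sequencing of every animal is too expensive —
and need principled filters between "a SNP exists here" and "this
individual's genotype is trustworthy".

## What it computes

For a multi-sample call set (VCF with GT/AD/DP), per site:

- **Hard site filters** — quality by depth QD = QUAL/depth and the
  phred-scaled Fisher strand bias FS = −10 log₁₀(p), with the RNA profile
  *fail iff QD < 2 or FS > 30*;
- **Genotype call-rate metrics** — CR (fraction of individuals with a
  genotype) and the depth-conditioned *(k.reads.DP) genotype CR* (fraction
  of all individuals with a ≥ k-read genotype), with the selection rule
  *(5.reads.DP) CR ≥ 20% and CR ≥ 50%*, then MAF ≥ 10% and, for ASE,
  heterozygosity in ≥ 25% of the population;
- **Concordance vs DNA-seq** — detection precision/recall and genotype
  concordance as a function of (CR, depth) thresholds, plus multi-tissue
  genotype merging (highest-depth call wins on discordance);
- **Context flags** — SNP clusters (≥ 3 SNPs / 35 bp, flagged not
  removed), homopolymer runs (≥ 5 bases), splice-junction proximity
  (≤ 5 exonic bases), and CDS/UTR/exon/intron/intergenic classification;
- **Expression threshold** — exon RpKb (reads per kilobase) scored as
  log₁₀(RpKb + 1) ≥ 0.5, justified against shuffled background loci ≥ 5 kb
  from any gene;
- **ASE** — per-gene "super-allele" read counts, exact binomial test
  against 0.5 per sample, Benjamini–Hochberg per sample across genes at
  FDR 0.05, gene called ASE when significant in ≥ 2 samples;
- **Population summaries** — tiered SNP accounting with ratios and means,
  cross-population union/intersection, consequence-severity and ALT/ALT
  frequency profiles, and identity-by-state average-linkage clustering.

A synthetic-data generator (`sim_config()`, `emit_callsets()`) draws a toy
genome with exon/intron structure, Hardy–Weinberg population truth,
Poisson depth proportional to TPM for the RNA assay (uniform 20X for the
DNA assay), binomial allele counts with base error, strand-biased sites,
and cis-regulated genes with configurable allelic fold change — so the
whole pipeline is testable offline. The `vignettes/` directory documents
the models and every threshold; `analysis/01_simulate.R` …
`analysis/08_popgen.R` run the stages as a narrative workflow and write
their tables under `results/`.

## Worked example

```r
library(exprvar)

cfg <- sim_config(seed = 20260101, n_individuals = 15, n_genes = 30,
                  tissues = c("liver", "blood", "hypothalamus"))
sim <- emit_callsets(cfg, "simdata")

rna <- apply_filter_profile(select_biallelic_snps(sim$callsets$rna_liver),
                            "rna", strict = TRUE)
sel <- select_genotyped_sites(rna, k = 5, dp_cr_min = 0.20, cr_min = 0.50)
maf <- maf_filter(sel, 0.10)
nrow(rna$sites); nrow(sel$sites); nrow(maf$sites)
#> [1] 140
#> [1] 83
#> [1] 62

genotype_concordance(rna, sim$callsets$dna, dp_min = 5)$concordance
#> [1] 99.06103
```

140 biallelic SNPs survive the site filters; 83 of them have a reliable
population genotype (5-read CR ≥ 20%, CR ≥ 50%) and 62 also have
MAF ≥ 10%. Genotypes supported by ≥ 5 reads agree with the uniform-20X DNA
assay for 99.1% of comparable (site, individual) pairs — the depth filter
is what buys that reliability: without it (dp_min = 0) concordance drops
to 96.8%, and the acceptance run below shows the same ordering across ten
simulation seeds.

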