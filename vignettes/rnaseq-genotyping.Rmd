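---
title: "Genotyping a population from RNA-seq: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping a population from RNA-seq: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprvar)
```

## The problem

DNA re-sequencing covers a genome roughly uniformly, so a 20X experiment
genotypes essentially every individual at every SNP. RNA-seq coverage is a
function of gene expression: read depth at a site ranges from thousands of
reads in a highly expressed exon to zero in a silent gene, with introns of
immature transcripts weakly covered in between. The consequence is a split
between *detection* and *genotyping*: a SNP can be discovered at the
population level by pooling reads across individuals while most individuals
still lack the per-sample depth needed for a genotype. `exprvar` implements
a complete filtering pipeline around that asymmetry — site-level hard
filters, depth-conditioned genotype call-rate selection, concordance
evaluation against a DNA assay, sequence-context flags, an expression
threshold, allele-specific expression (ASE) calling and population
summaries — together with a simulator that reproduces the
expression-dependent coverage so every stage can be tested end to end
without sequencing data.

## The coverage and genotyping model

The simulator draws, for each site $s$ and individual $i$:

* DNA assay: $DP_{si} \sim \mathrm{Poisson}(\mu_{DNA})$ with
  $\mu_{DNA} = 20$ by default;
* RNA assay: $DP_{si} \sim \mathrm{Poisson}(c \cdot TPM_g)$ for exonic
  sites of gene $g$ (library factor $c = 1$ read per TPM by default), a
  fraction (5%) of that for intronic sites, and a mapping-noise floor
  (0.1 reads) for untranscribed positions;
* alt reads $\sim \mathrm{Binomial}(DP_{si}, q)$ with
  $q \in \{\varepsilon,\ 1/2,\ 1-\varepsilon\}$ for hom-ref / het /
  hom-alt truth ($\varepsilon = 0.005$ per base), the het ratio replaced
  by the phase-consistent cis-skewed ratio in ASE genes.

Truth genotypes are Hardy–Weinberg draws from a folded Beta(0.5, 0.5)
allele-frequency spectrum, sites are independent (no linkage), and TPM is
log-normal (meanlog 2, sdlog 1.5), re-drawn per tissue at correlation 0.8.
These defaults were fixed once as a caricature of a 15-individual livestock
cohort; nothing in the test suite tunes them.

The emitted call sets come from a deliberately simple maximum-likelihood
binomial genotyper: a genotype is missing ("./.") below 3 reads, otherwise
the likelihood-maximising class is called, and a site is emitted only when
at least one sample carries a called non-ref genotype. The 3-read caller
minimum is a simulator parameter, *not* an analysis threshold: production
callers have an internal minimum-evidence behaviour whose exact rule is
undocumented, so we expose it rather than assert it. It is deliberately
distinct from the 5-read analysis filter below, so low-depth missingness
arises in the data rather than being imposed by the pipeline.

## Site filters

Two hard filters are applied to RNA call sets, with strict comparisons
exactly as usually printed: fail iff $QD < 2$ or $FS > 30$. The DNA
profile uses the conventional six thresholds (FS > 60, QD < 2, SOR > 3,
MQ < 40, MQRankSum < −12.5, ReadPosRankSum < −8). Missing optional
statistics never fail a site — callers omit rank sums at many records, and
failing on absence would silently drop valid sites.

`FS` is the phred-scaled two-sided Fisher exact p-value of the
ref/alt × forward/reverse table. We use the conditional exact definition
(sum of hypergeometric probabilities of tables, at the observed margins,
no more probable than the observed one), with the customary $1+10^{-7}$
relative tolerance when comparing probabilities for ties, and the p-value
floored at $10^{-300}$ before the $-10\log_{10}$ transform. The
implementation is vectorised over tables via `dhyper`; tests compare it
against both `stats::fisher.test` and an independent `lchoose`-based
enumeration of every 2×2 table with margins ≤ 30 (agreement to $10^{-9}$).

The third commonly suggested RNA-seq criterion — three or more SNPs in a
35-bp window — is a *flag*, not a filter: removing clusters discards too
many SNPs confirmed by DNA for the precision it buys.

## Genotype selection

Per site, with $n$ the population size:

* call rate $CR$ = fraction of individuals with a called genotype;
* $(k.reads.DP)$ genotype $CR$ = fraction of **all** individuals whose
  genotype is called *and* supported by ≥ k reads.

The all-samples denominator in the second metric is what makes the two
axes of the selection surface differ; reading it as "fraction of the
population with a ≥ k-read genotype" keeps the two metrics comparable and
the inequality $dpCR_k \le CR$ exact. Selection keeps sites with
$(5.reads.DP)\,CR \ge 20\%$ and $CR \ge 50\%$, both inclusive. Allele
frequencies are computed over called genotypes only
($af = (n_{het} + 2 n_{homalt}) / 2n_{called}$), MAF = min(af, 1−af) with
an inclusive 10% filter, and the ASE-oriented heterozygosity filter keeps
sites het in ≥ 25% of the population — denominator all samples, because
"of the population" reads population-wide, not called-only. Percentages in
reports are truncated toward zero (1/6 renders as 16%), matching how call
rates are conventionally quoted; internal values stay exact fractions.

## Concordance evaluation

Detection precision/recall and genotype concordance treat the DNA assay as
truth. Site identity always includes the alt allele, so a discordant
alternate allele is never credited. Concordance compares only pairs where
both assays called a genotype and the test depth clears the threshold;
reference genotypes are used unfiltered. Multi-tissue merging keeps, per
site and sample, the single-tissue call, a concordant multi-tissue call,
or — on discordance — the call of the tissue with the highest depth, ties
resolved to the first tissue in input order and counted (the tie rule is
declared, not inferred from any source; ties are rare).

## Sequence context

* *SNP clusters*: a SNP is flagged iff some 35-bp window containing it
  holds ≥ 3 SNPs. The wording of the window rule is ambiguous about
  whether bystander SNPs inside a qualifying window are flagged; we flag
  every SNP contained in any qualifying window — conservative and
  brute-force checkable.
* *Homopolymers*: maximal single-base runs of length ≥ 5; a SNP is
  flagged iff strictly inside a run (a `pad` argument can extend runs for
  users who want the adjacent-base reading).
* *Junction proximity*: within 5 *exonic* bases of a splice boundary
  (last 5 bases of the upstream exon, first 5 of the downstream exon).
  Intronic positions are never flagged: the concern is exonic mapping
  error near splice sites.
* *Feature class*: precedence CDS > UTR5 > UTR3 > non-coding exon >
  intron > intergenic when a SNP overlaps several annotations, so the
  classes partition the SNP set.

Enrichment comparisons between call-set categories use a 2×2 Pearson
chi-square without continuity correction — the compared counts are large
in the intended use.

## Expression threshold

Exon expression is scored as RpKb (mean mapped reads across samples per
kilobase of exon) on the $\log_{10}(RpKb+1)$ scale, and exons with score
≥ 0.5 (inclusive) form the expressed mask. The threshold is fixed at 0.5
rather than re-derived per dataset; the first quartile of the exon score
distribution (type-7 linear-interpolation quantile, the R default — a
convention that must be pinned for reproducibility) and the score
distribution of shuffled background loci (placed ≥ 5 kb from any gene,
lengths drawn from a supplied pool) are reported alongside so the choice
is auditable. In the simulator the background is driven by the
mapping-noise floor, keeping the comparison non-degenerate.

## ASE calling

Per gene and sample, reads are pooled over one haplotype ("super-allele")
pair. When per-SNP phased counts are supplied, the block covering the most
SNPs is selected (ties: most reads, then leftmost) — a declared stand-in
for the phasing tool's unspecified internal choice. A sample is eligible
when the larger super-allele has ≥ 10 reads (the literal reading of the
rule; `min_reads_mode = "total"` switches to the ≥ 10-total reading).
Eligible samples get a two-sided exact binomial test against 0.5;
p-values are BH-adjusted **per sample across genes** (the alternative, one
global correction, changes results and does not match the per-sample
counting of significant samples); a gene is ASE iff significant at
q ≤ 0.05 in ≥ 2 samples. Reported |log2 aFC| uses a 0.5 pseudocount on
both counts so extreme counts stay finite; the test itself uses raw
counts.

In the recovery benchmark (10 replicates of 500 genes × 8 individuals at
mean haplotypic depth 100) sensitivity is measured among cis-regulated
genes with true |aFC| ≥ 2 that are *detectable by design* — genes with at
least two samples that both carry the regulatory heterozygote and pass
read eligibility. A gene whose imbalance is expressed in fewer than two
samples cannot reach the two-sample call threshold whatever the test
does, so including such genes would measure the simulated allele-frequency
lottery rather than the test; the raw and conditional counts are both
computed in the acceptance script. The empirical FDR is the fraction of
called genes that are not truly cis-regulated.

## Population summaries

The accounting table machinery reproduces tiered per-population counts
with multi/single-tissue and tier ratios rounded to 2 decimals, count
means rounded to integers, and ratio means taken over the rounded column.
Cross-population union/intersection operates on (chrom, pos, ref, alt)
keys. Consequence severity sums stop-gained, splice-site, SIFT-deleterious
missense (score ≤ 0.05) and start/stop-lost predictions; prediction
algorithms themselves are external — the package owns only the accounting.
The ALT/ALT profile classifies a variant over the populations carrying its
alt allele: absent (hom-alt frequency 0 everywhere) or low (maximum ≤ 5%);
reported percentages round to the nearest integer.

Identity-by-state uses
$IBS(i,j) = \overline{(2 - |d_i - d_j|)/2}$ over sites called in both
individuals ($d$ = alt dosage), distance $1 - IBS$, average-linkage
agglomeration; the metric is fixed and documented here because clustering
functions in the field's toolkits leave it implicit.

## Numerical and degenerate-input conventions

* Fisher p = 1 for degenerate tables (empty row or column); p floored at
  $10^{-300}$; tie tolerance $1+10^{-7}$.
* QD = 0 at zero informative depth; negative quality is an error.
* Sites with no called genotype have undefined frequencies and are
  flagged, not silently dropped.
* Half-called genotypes ("0/.") are treated as missing and counted
  (`attr(, "n_half_calls")`): their intended semantics are
  caller-dependent and undocumented.
* Multi-allelic genotypes are carried as non-ref dosage until biallelic
  selection, which every downstream stage assumes.
* Per-genotype depth comes from FORMAT/DP when present, else the AD sum,
  else 0 — an explicit, testable precedence across caller dialects.
* All internal coordinates are 0-based half-open; VCF positions and GTF
  intervals are converted at the boundary.

## What the simulation does and does not show

The generator reproduces the features the pipeline's logic depends on:
expression-dependent depth, intronic under-coverage, binomial allele
sampling with base error, strand-biased sites for the FS filter,
HWE genotype structure, cis-regulated allelic imbalance with phase
consistency, and multi-tissue TPM correlation. It does not model linkage
disequilibrium, population structure or pedigrees, mapping artefacts
(multi-mapping, reference bias), RNA editing, or read-level error
correlation. Passing tests therefore demonstrate that the *computations*
are correct and that parameter recovery behaves as designed under the
stated model — not that the thresholds are optimal for any particular real
dataset, where mapping bias and LD can move precision and concordance.

Test and acceptance problem sizes — a 30-gene toy genome (~140 kb,
~700 sites, 15 individuals) for pipeline runs, 10 seeds for concordance
ordering, 10 × 500 genes × 8 samples for ASE recovery, 2 × 6 individuals
× 2,000 sites × 10 replicates for IBS clustering — were chosen as the
smallest sizes at which the sampling noise of each measured quantity is
comfortably below its acceptance margin.

## Known limitations

* The VCF writer emits the fields the pipeline uses (GT:AD:DP, QD/FS and
  pass-through statistics); it is not a general-purpose VCF serialiser.
* The simulated caller's QUAL is a pooled likelihood ratio; its scale is
  internally consistent but not calibrated to any production caller.
* `merge_tissues` holds all union sites in memory; it is sized for
  cohort-scale call sets, not biobank-scale ones.
* Background-locus placement is rejection sampling; genomes that are
  nearly all genic need a smaller `min_dist` or fail loudly with
  diagnostics.
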