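#!/usr/bin/env Rscript
# Sequence/annotation context of the selected SNPs: cluster, homopolymer
# and junction flags, feature classification, and an enrichment comparison
# of junction proximity between RNA-only and DNA-only detections.

suppressMessages(library(exprvar))

genome <- read_fasta("results/simdata/genome.fa")
models <- read_annotation("results/simdata/annotation.gtf", "gtf")
dna <- read_vcf("results/simdata/dna.vcf")
rna <- apply_filter_profile(select_biallelic_snps(
  read_vcf("results/simdata/rna_liver.vcf")), "rna", strict = TRUE)

ann <- annotate_context(rna, models, genome)
write.table(ann$sites, "results/context_flags.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Feature classes of the RNA-detected SNPs:\n")
print(round(100 * prop.table(table(ann$sites$feature_class))))
cat(sprintf("Flags: %.1f%% in SNP clusters, %.1f%% in homopolymers, %.1f%% near junctions.\n",
            100 * mean(ann$sites$in_cluster),
            100 * mean(ann$sites$in_homopolymer),
            100 * mean(ann$sites$near_junction)))

# junction-proximity enrichment: RNA-only vs DNA-only detections
rna_keys <- site_keys(rna); dna_keys <- site_keys(dna)
ann_dna <- annotate_context(dna, models, genome)
rna_only <- !(rna_keys %in% dna_keys)
dna_only <- !(dna_keys %in% rna_keys)
if (any(rna_only) && any(dna_only)) {
  enr <- flag_enrichment(sum(ann$sites$near_junction[rna_only]), sum(rna_only),
                         sum(ann_dna$sites$near_junction[dna_only]), sum(dna_only))
  cat(sprintf("Junction-proximity prevalence RNA-only %.2f%% vs DNA-only %.2f%% (ratio %s, chi2 p = %.3g)\n",
              100 * enr$prevalence_a, 100 * enr$prevalence_b,
              ifelse(is.na(enr$ratio), "NA", sprintf("%.2f", enr$ratio)),
              enr$p_value))
}
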