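#' Pipeline configuration
#'
#' Bundles the simulation config with every stage threshold and validates
#' ranges. Defaults are the workflow's operating point: RNA hard filters
#' QD < 2 / FS > 30, genotype selection (5.reads.DP) CR >= 20% and
#' CR >= 50%, MAF >= 10%, het prevalence >= 25%, expression threshold
#' log10(RpKb + 1) >= 0.5, cluster window 35 bp / 3 SNPs, junction flank
#' 5 bp, homopolymer length >= 5, ASE: >= 10 reads, FDR 0.05, >= 2
#' significant samples.
#'
#' @param sim a [sim_config()].
#' @param out_dir output directory for stage artifacts.
#' @param qd_min,fs_max RNA site-filter thresholds.
#' @param k,dp_cr_min,cr_min genotype selection thresholds (fractions).
#' @param maf_min,het_min frequency thresholds (fractions).
#' @param expr_threshold expressed-exon log score threshold.
#' @param cluster_window,cluster_min_snps,junction_dist,hp_min_len context
#'   parameters.
#' @param ase_min_reads,ase_fdr,ase_min_samples ASE parameters.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), out_dir = tempfile("exprvar_"),
                            qd_min = 2, fs_max = 30,
                            k = 5, dp_cr_min = 0.20, cr_min = 0.50,
                            maf_min = 0.10, het_min = 0.25,
                            expr_threshold = 0.5,
                            cluster_window = 35, cluster_min_snps = 3,
                            junction_dist = 5, hp_min_len = 5,
                            ase_min_reads = 10, ase_fdr = 0.05,
                            ase_min_samples = 2) {
  fracs <- c(dp_cr_min = dp_cr_min, cr_min = cr_min, maf_min = maf_min,
             het_min = het_min, ase_fdr = ase_fdr)
  if (any(fracs < 0 | fracs > 1))
    stop("fraction thresholds must lie in [0, 1]: ",
         paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  if (k < 0 || ase_min_reads < 0 || cluster_window < 1 || cluster_min_snps < 1)
    stop("count thresholds must be non-negative")
  structure(as.list(environment())[
    c("sim", "out_dir", "qd_min", "fs_max", "k", "dp_cr_min", "cr_min",
      "maf_min", "het_min", "expr_threshold", "cluster_window",
      "cluster_min_snps", "junction_dist", "hp_min_len", "ase_min_reads",
      "ase_fdr", "ase_min_samples")],
    class = "pipeline_config")
}

#' Run the pipeline end to end on simulated data
#'
#' simulate -> site-filter -> genotype-filter -> concordance vs the DNA
#' assay -> context annotation -> expression threshold -> ASE -> summary,
#' writing per-stage artifacts and a reproducibility manifest (seed,
#' thresholds, per-file MD5 checksums, per-stage site counters) under
#' `config$out_dir`. Deterministic: identical config implies identical
#' checksums.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the main in-memory results and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_counts <- list()

  sim <- emit_callsets(config$sim, config$out_dir)
  rna_name <- paste0("rna_", config$sim$tissues[1])
  rna <- sim$callsets[[rna_name]]
  dna <- sim$callsets$dna
  log_counts$sites_emitted_rna <- nrow(rna$sites)
  log_counts$sites_emitted_dna <- nrow(dna$sites)

  rna <- select_biallelic_snps(rna)
  rna <- apply_filter_profile(rna, "rna", strict = TRUE)
  log_counts$sites_after_site_filters <- nrow(rna$sites)

  selected <- select_genotyped_sites(rna, k = config$k,
                                     dp_cr_min = config$dp_cr_min,
                                     cr_min = config$cr_min)
  log_counts$sites_selected_gt <- nrow(selected$sites)
  maf_sel <- maf_filter(selected, config$maf_min)
  log_counts$sites_selected_maf <- nrow(maf_sel$sites)

  metrics <- cbind(selected$sites[, c("chrom", "pos", "ref", "alt")],
                   site_gt_metrics(selected, k = config$k))
  utils::write.table(metrics, file.path(config$out_dir, "site_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_vcf(selected, file.path(config$out_dir, "selected.vcf"))

  conc <- genotype_concordance(rna, dna, dp_min = config$k,
                               cr_min = config$cr_min)
  pr <- detection_precision_recall(rna, dna)

  ann <- annotate_context(selected, sim$genome$models, sim$genome$genome,
                          window = config$cluster_window,
                          min_snps = config$cluster_min_snps,
                          hp_min_len = config$hp_min_len,
                          junction_dist = config$junction_dist)
  utils::write.table(ann$sites, file.path(config$out_dir, "context.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  bg <- generate_background_loci(
    sim$genome$models,
    stats::setNames(nchar(sim$genome$genome), names(sim$genome$genome)),
    n = 20, length_pool = 200:800, min_dist = 1000)
  xc <- simulate_exon_counts(config$sim, sim$truth, sim$genome$models, bg)
  expr <- compute_rpkb(xc$exon_counts, xc$exon_lengths, xc$exon_id)
  bg_expr <- compute_rpkb(xc$bg_counts, xc$bg_lengths)
  sel_ex <- select_expressed_exons(expr, config$expr_threshold,
                                   bg_expr$log_score)
  utils::write.table(expr, file.path(config$out_dir, "exon_expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_counts$exons_expressed <- nrow(sel_ex$expressed)

  hap <- simulate_gene_haplotype_counts(config$sim, sim$truth)
  ase <- call_ase_genes(hap, fdr = config$ase_fdr,
                        min_reads = config$ase_min_reads,
                        min_samples = config$ase_min_samples)
  utils::write.table(ase$genes, file.path(config$out_dir, "ase_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_counts$genes_ase <- sum(ase$genes$is_ase)

  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("exprvar")),
    seed = config$sim$seed,
    thresholds = config[!(names(config) %in% c("sim", "out_dir"))],
    stage_counters = log_counts,
    checksums = as.list(tools::md5sum(sort(files))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(callsets = sim$callsets, truth = sim$truth,
                 selected = selected, maf_selected = maf_sel,
                 concordance = conc, precision_recall = pr,
                 context = ann$sites, expression = sel_ex, ase = ase,
                 manifest = manifest))
}
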