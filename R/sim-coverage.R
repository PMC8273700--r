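#' Simulate per-assay read depth and allele counts
#'
#' DNA assay: depth ~ Poisson(`dna_depth`) at every site and sample. RNA
#' assay (one per tissue): exonic depth ~ Poisson(`rna_libsize_factor` x
#' gene TPM); intronic depth at `intron_depth_fraction` of the gene's exonic
#' mean; untranscribed positions at the `noise_floor`. Alt reads are
#' Binomial(depth, q) with q = error for hom-ref, 1 - error for hom-alt, and
#' for hets 0.5 in DNA (and in non-cis genes in RNA) or the phase-consistent
#' cis-skewed ratio in RNA. Site-level strand counts are drawn read-wise
#' (forward with probability 0.5; alt reads of a random `strand_bias_fraction`
#' of sites use `strand_bias_p`) to exercise the Fisher-strand filter.
#'
#' @param cfg a [sim_config()].
#' @param truth a `sim_truth`.
#' @return list of assays. `$dna` and `$rna[[tissue]]` each hold `dp` and
#'   `alt` (sites x samples integer matrices) and `strand` (per-site
#'   ref_fwd/ref_rev/alt_fwd/alt_rev totals over the population).
#' @export
simulate_coverage_and_counts <- function(cfg, truth) {
  .stage_seed(cfg, "coverage")
  st <- truth$sites
  n_sites <- nrow(st)
  n <- length(truth$samples)
  eps <- cfg$error_rate

  gidx <- match(st$gene_id, truth$genes$gene_id)

  alt_prob <- function(assay_tissue) {
    # q0 = pre-error alt fraction per (site, sample)
    q0 <- matrix(0.5, n_sites, n)
    q0[truth$gt == 0] <- 0
    q0[truth$gt == 2] <- 1
    if (!is.null(assay_tissue)) {
      # cis skew for het sites of cis genes in regulatory-het individuals
      cis_site <- !is.na(gidx) & truth$genes$cis[gidx]
      if (any(cis_site)) {
        pi_up <- 2^abs(truth$genes$afc[gidx])  # expression share of up copy
        pi_up <- pi_up / (1 + pi_up)
        for (j in seq_len(n)) {
          het <- truth$gt[, j] == 1 & cis_site &
            truth$reg_gt[gidx, j] == 1
          if (!any(het)) next
          alt_on_hap1 <- truth$hap1[het, j] == 1
          up1 <- truth$hap_up[gidx[het], j] == 1
          # alt share = pi_up when alt sits on the up-regulated haplotype
          q0[het, j] <- ifelse(alt_on_hap1 == up1, pi_up[het], 1 - pi_up[het])
        }
      }
    }
    q0 * (1 - eps) + (1 - q0) * eps
  }

  draw_assay <- function(mean_dp, q) {
    dp <- matrix(stats::rpois(n_sites * n, mean_dp), n_sites, n,
                 dimnames = list(NULL, truth$samples))
    alt <- matrix(stats::rbinom(n_sites * n, as.vector(dp), as.vector(q)),
                  n_sites, n, dimnames = list(NULL, truth$samples))
    ref_tot <- rowSums(dp - alt)
    alt_tot <- rowSums(alt)
    biased <- stats::runif(n_sites) < cfg$strand_bias_fraction
    p_alt_fwd <- ifelse(biased, cfg$strand_bias_p, 0.5)
    ref_fwd <- stats::rbinom(n_sites, ref_tot, 0.5)
    alt_fwd <- stats::rbinom(n_sites, alt_tot, p_alt_fwd)
    list(dp = dp, alt = alt,
         strand = data.frame(ref_fwd = ref_fwd, ref_rev = ref_tot - ref_fwd,
                             alt_fwd = alt_fwd, alt_rev = alt_tot - alt_fwd))
  }

  dna <- draw_assay(cfg$dna_depth, alt_prob(NULL))

  rna <- list()
  for (t in cfg$tissues) {
    tpm_site <- ifelse(is.na(gidx), 0, truth$tpm[cbind(gidx, match(t, cfg$tissues))])
    mean_dp <- cfg$rna_libsize_factor * tpm_site
    mean_dp[st$feature_class == "intronic"] <-
      mean_dp[st$feature_class == "intronic"] * cfg$intron_depth_fraction
    mean_dp <- pmax(mean_dp, cfg$noise_floor)
    mean_dp[st$feature_class == "intergenic"] <- cfg$noise_floor
    rna[[t]] <- draw_assay(rep(mean_dp, n), alt_prob(t))
  }
  list(dna = dna, rna = rna)
}

#' Emit call sets from simulated counts
#'
#' A deliberately simple maximum-likelihood binomial genotyper standing in
#' for a production caller: per sample and site, if depth is below
#' `gt_call_min_dp` the genotype is missing ("./."); otherwise the genotype
#' maximising the binomial likelihood of the alt count under alt-read
#' probabilities {error, 0.5, 1 - error} is called — so low-depth
#' missingness arises naturally from the coverage model. A site is emitted
#' (discovered) iff at least one sample carries a called non-ref genotype.
#' QUAL is the phred-scaled pooled likelihood ratio against all-hom-ref; QD
#' normalises QUAL by the depth of non-ref-called samples; FS comes from the
#' simulated strand table.
#'
#' @param cfg a [sim_config()].
#' @param assay one element of [simulate_coverage_and_counts()] output
#'   (e.g. `counts$dna` or `counts$rna[["liver"]]`).
#' @param truth the `sim_truth` used to generate the counts.
#' @return a [snp_callset()] of the emitted sites, with
#'   `attr(, "truth_rows")` giving the row of `truth$sites` behind each
#'   emitted record.
#' @export
emit_callset <- function(cfg, assay, truth) {
  eps <- max(cfg$error_rate, 1e-12)  # keep log-likelihoods finite at error 0
  dp <- assay$dp; alt <- assay$alt
  n_sites <- nrow(dp); n <- ncol(dp)
  ll <- function(q) alt * log(q) + (dp - alt) * log(1 - q)
  ll0 <- ll(eps); ll1 <- ll(0.5); ll2 <- ll(1 - eps)
  gt <- (ll1 > ll0 & ll1 >= ll2) * 1L + (ll2 > ll0 & ll2 > ll1) * 2L
  gt[dp < cfg$gt_call_min_dp] <- NA_integer_
  dimnames(gt) <- dimnames(dp)

  best <- pmax(ll0, ll1, ll2)
  nonref <- !is.na(gt) & gt > 0
  qual_site <- rowSums((best - ll0) * nonref) * 10 / log(10)
  emitted <- rowSums(nonref) > 0

  info_dp <- rowSums(dp * nonref)
  qd <- quality_by_depth(qual_site, info_dp)
  sdf <- assay$strand
  fs <- fisher_strand_phred(sdf$ref_fwd, sdf$ref_rev, sdf$alt_fwd, sdf$alt_rev)

  st <- truth$sites
  sites <- data.frame(chrom = st$chrom, pos = st$pos, id = NA_character_,
                      ref = st$ref, alt = st$alt, qual = qual_site,
                      filter = ".", qd = qd, fs = fs,
                      stringsAsFactors = FALSE)
  out <- snp_callset(sites[emitted, , drop = FALSE],
                     gt[emitted, , drop = FALSE],
                     dp[emitted, , drop = FALSE],
                     (dp - alt)[emitted, , drop = FALSE],
                     alt[emitted, , drop = FALSE],
                     truth$samples)
  attr(out, "truth_rows") <- which(emitted)
  out
}

#' Emit all call sets and truth tables to a directory
#'
#' Convenience wrapper writing one VCF per assay/tissue plus tab-separated
#' truth tables (sites, genotypes, gene TPM, cis truth), the toy reference
#' FASTA and GTF. With a fixed config seed all files are byte-identical
#' across runs.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory objects (`genome`, `truth`,
#'   `counts`, `callsets`) and the written `paths`.
#' @export
emit_callsets <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- build_toy_genome(cfg)
  truth <- simulate_population_truth(cfg, genome)
  counts <- simulate_coverage_and_counts(cfg, truth)
  callsets <- list(dna = emit_callset(cfg, counts$dna, truth))
  for (t in cfg$tissues)
    callsets[[paste0("rna_", t)]] <- emit_callset(cfg, counts$rna[[t]], truth)

  paths <- list(fasta = file.path(out_dir, "genome.fa"),
                gtf = file.path(out_dir, "annotation.gtf"),
                sites = file.path(out_dir, "truth_sites.tsv"),
                gt = file.path(out_dir, "truth_genotypes.tsv"),
                tpm = file.path(out_dir, "truth_tpm.tsv"),
                genes = file.path(out_dir, "truth_genes.tsv"))
  write_fasta(genome$genome, paths$fasta)
  write_gtf(genome$models, paths$gtf)
  utils::write.table(truth$sites, paths$sites, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gt_df <- cbind(truth$sites[, c("chrom", "pos")], as.data.frame(truth$gt))
  utils::write.table(gt_df, paths$gt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(gene_id = rownames(truth$tpm),
                                as.data.frame(truth$tpm)),
                     paths$tpm, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$genes, paths$genes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (nm in names(callsets)) {
    paths[[nm]] <- file.path(out_dir, paste0(nm, ".vcf"))
    write_vcf(callsets[[nm]], paths[[nm]])
  }
  invisible(list(genome = genome, truth = truth, counts = counts,
                 callsets = callsets, paths = paths))
}

#' Simulate per-gene haplotype ("super-allele") read counts
#'
#' For each gene and sample the total haplotypic read count is
#' Poisson(`rna_libsize_factor` x TPM); haplotype-A reads are
#' Binomial(total, pi) with pi = 0.5 for non-cis genes (and for individuals
#' homozygous at the regulatory variant) and pi = 2^aFC / (1 + 2^aFC) for
#' heterozygous carriers of a cis-regulated gene, signed by which haplotype
#' carries the up-regulated copy.
#'
#' @param cfg a [sim_config()].
#' @param truth a `sim_truth`.
#' @param tissue tissue whose TPM drives the counts.
#' @return data.frame `gene_id`, `sample`, `count_hapA`, `count_hapB`,
#'   `n_snps_in_haplotype`, plus the per-cell truth columns `cis_active`
#'   (cis gene and regulatory het) and `true_afc`.
#' @export
simulate_gene_haplotype_counts <- function(cfg, truth, tissue = cfg$tissues[1]) {
  .stage_seed(cfg, "hapcounts")
  g <- truth$genes
  ng <- nrow(g); n <- length(truth$samples)
  tpm <- truth$tpm[, match(tissue, cfg$tissues)]
  total <- matrix(stats::rpois(ng * n, rep(cfg$rna_libsize_factor * tpm, n)),
                  ng, n)
  active <- g$cis & truth$reg_gt == 1
  pi_up <- 2^g$afc / (1 + 2^g$afc)          # share of haplotype carrying "up"
  pi_a <- matrix(0.5, ng, n)
  up1 <- truth$hap_up == 1
  pi_a[active & up1] <- rep(pi_up, n)[active & up1]
  pi_a[active & !up1] <- rep(1 - pi_up, n)[active & !up1]
  hapA <- matrix(stats::rbinom(ng * n, as.vector(total), as.vector(pi_a)), ng, n)
  exonic_het <- matrix(0L, ng, n)
  ex_sites <- truth$sites$feature_class == "exonic" & !is.na(truth$sites$gene_id)
  if (any(ex_sites)) {
    het <- (truth$gt == 1)[ex_sites, , drop = FALSE]
    gids <- truth$sites$gene_id[ex_sites]
    for (j in seq_len(n)) {
      tab <- tapply(het[, j], gids, sum)
      exonic_het[match(names(tab), g$gene_id), j] <- as.integer(tab)
    }
  }
  data.frame(gene_id = rep(g$gene_id, n),
             sample = rep(truth$samples, each = ng),
             count_hapA = as.vector(hapA),
             count_hapB = as.vector(total - hapA),
             n_snps_in_haplotype = as.vector(exonic_het),
             cis_active = as.vector(active),
             true_afc = rep(g$afc, n),
             stringsAsFactors = FALSE)
}
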