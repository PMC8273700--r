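#' Simulate the population ground truth
#'
#' Places SNP sites by feature class at the configured per-kb densities,
#' draws each site's alt-allele frequency from the folded Beta spectrum, and
#' samples two haplotype alleles per individual independently (Hardy-Weinberg
#' proportions, no linkage). Per-gene TPM is log-normal, re-drawn per tissue
#' at the configured log-scale correlation; a fraction of genes is flagged
#' cis-regulated with a signed log2 allelic fold change and a regulatory
#' variant whose heterozygous carriers express the imbalance. Within each
#' carrier the up-regulated copy is haplotype 1 or 2 at random, fixed for
#' all sites of the gene (phase-consistent).
#'
#' @param cfg a [sim_config()].
#' @param genome output of [build_toy_genome()].
#' @return list of class `sim_truth`: `sites` (chrom, pos 1-based, pos0,
#'   ref, alt, af, feature_class, gene_id), `hap1`/`hap2` (sites x
#'   individuals 0/1 matrices), `gt` (= hap1 + hap2), `genes` (biotype, cis,
#'   afc, TPM per tissue), `reg_gt` (genes x individuals regulatory
#'   genotype), `hap_up` (genes x individuals; which haplotype, 1 or 2,
#'   carries the up-regulated copy), `samples`.
#' @export
simulate_population_truth <- function(cfg, genome) {
  .stage_seed(cfg, "truth")
  regions <- .genome_regions(genome$genome, genome$models)
  chrom <- names(genome$genome)[1]
  seqc <- strsplit(genome$genome[[1]], "")[[1]]

  place <- function(iv, density_kb, class) {
    if (!nrow(iv)) return(NULL)
    widths <- iv$end - iv$start
    n <- stats::rpois(1, sum(widths) / 1000 * density_kb)
    if (n == 0) return(NULL)
    # sample positions uniformly over the union of intervals
    offs <- sort(sample.int(sum(widths), min(n, sum(widths))))
    cum <- cumsum(widths)
    idx <- findInterval(offs - 1L, c(0L, cum[-length(cum)]))
    pos0 <- iv$start[idx] + (offs - 1L - c(0L, cum)[idx])
    data.frame(chrom = chrom, pos0 = pos0, feature_class = class,
               stringsAsFactors = FALSE)
  }
  sites <- rbind(place(regions$exonic, cfg$site_density_kb[["exonic"]], "exonic"),
                 place(regions$intronic, cfg$site_density_kb[["intronic"]], "intronic"),
                 place(regions$intergenic, cfg$site_density_kb[["intergenic"]], "intergenic"))
  sites <- sites[!duplicated(sites$pos0), , drop = FALSE]
  sites <- sites[order(sites$pos0), , drop = FALSE]
  n_sites <- nrow(sites)
  sites$pos <- sites$pos0 + 1L
  sites$ref <- seqc[sites$pos]
  other <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG", N = "ACG")
  pick <- sample.int(3, n_sites, replace = TRUE)
  sites$alt <- substring(other[sites$ref], pick, pick)

  p <- stats::rbeta(n_sites, cfg$maf_beta[1], cfg$maf_beta[2])
  sites$af <- pmin(p, 1 - p)  # folded: alt is the minor allele at generation

  # gene assignment of genic sites
  g <- genome$models$genes
  gi <- rep(NA_character_, n_sites)
  for (k in seq_len(nrow(g))) {
    inside <- sites$pos0 >= g$start[k] & sites$pos0 < g$end[k]
    gi[inside] <- g$gene_id[k]
  }
  sites$gene_id <- gi

  n <- cfg$n_individuals
  samples <- sprintf("ind%02d", seq_len(n))
  hap1 <- matrix(stats::rbinom(n_sites * n, 1, rep(sites$af, n)), n_sites, n)
  hap2 <- matrix(stats::rbinom(n_sites * n, 1, rep(sites$af, n)), n_sites, n)
  colnames(hap1) <- colnames(hap2) <- samples

  # gene expression and cis-regulation truth
  ng <- nrow(g)
  nt <- length(cfg$tissues)
  base_z <- stats::rnorm(ng)
  tpm <- matrix(0, ng, nt, dimnames = list(g$gene_id, cfg$tissues))
  for (t in seq_len(nt)) {
    z <- if (t == 1) base_z else
      cfg$tissue_cor * base_z + sqrt(1 - cfg$tissue_cor^2) * stats::rnorm(ng)
    tpm[, t] <- exp(cfg$tpm_meanlog + cfg$tpm_sdlog * z)
  }
  cis <- stats::runif(ng) < cfg$ase_fraction
  afc <- ifelse(cis,
                sample(c(-1, 1), ng, replace = TRUE) *
                  stats::runif(ng, cfg$afc_range[1], cfg$afc_range[2]),
                0)
  reg_p <- stats::runif(ng, 0.2, 0.5)
  reg_gt <- matrix(stats::rbinom(ng * n, 2, rep(reg_p, n)), ng, n,
                   dimnames = list(g$gene_id, samples))
  hap_up <- matrix(sample(1:2, ng * n, replace = TRUE), ng, n,
                   dimnames = list(g$gene_id, samples))

  genes <- data.frame(gene_id = g$gene_id, biotype = g$biotype,
                      cis = cis, afc = afc, stringsAsFactors = FALSE)
  structure(list(sites = sites[, c("chrom", "pos", "pos0", "ref", "alt", "af",
                                   "feature_class", "gene_id")],
                 hap1 = hap1, hap2 = hap2, gt = hap1 + hap2,
                 genes = genes, tpm = tpm, reg_gt = reg_gt, hap_up = hap_up,
                 samples = samples),
            class = "sim_truth")
}
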