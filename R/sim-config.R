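#' Simulation configuration
#'
#' Defines the study conditions the synthetic data emulates: a small
#' population genotyped both by a uniform-depth "DNA-seq-like" assay and by
#' an expression-dependent "RNA-seq-like" assay in one or more tissues.
#'
#' Coverage model: the DNA assay draws per-site, per-sample depth from
#' Poisson(`dna_depth`); the RNA assay draws exonic depth from
#' Poisson(`rna_libsize_factor` x gene TPM), intronic depth at
#' `intron_depth_fraction` of the exonic mean (premature transcripts), and
#' intergenic depth at the mapping-noise floor. Alt reads are binomial with
#' per-base error `error_rate`; a fraction `ase_fraction` of genes are
#' cis-regulated with |log2 allelic fold change| drawn uniformly from
#' `afc_range`, which skews the allelic ratio in heterozygous carriers
#' consistently with haplotype phase.
#'
#' @param seed integer seed; a fixed seed makes every emitted file
#'   byte-identical across runs.
#' @param n_individuals population size (default 15, a typical RNA-seq
#'   cohort for one tissue).
#' @param n_genes number of genes on the toy chromosome.
#' @param exons_per_gene range of exon counts per gene.
#' @param exon_length,intron_length,intergenic_gap base-pair ranges.
#' @param prop_coding fraction of genes that are protein-coding (rest lncRNA).
#' @param maf_beta Beta(a, b) parameters of the site allele-frequency
#'   spectrum; draws are folded to <= 0.5.
#' @param site_density_kb named vector of SNP densities per kb for
#'   `exonic`, `intronic`, `intergenic` sequence.
#' @param dna_depth mean uniform DNA-seq depth (20X as in a standard
#'   re-sequencing design).
#' @param rna_libsize_factor reads of exonic depth per TPM unit.
#' @param tpm_meanlog,tpm_sdlog log-normal parameters of gene TPM.
#' @param intron_depth_fraction exon-to-intron depth ratio (default 0.05:
#'   immature transcripts are weakly covered).
#' @param noise_floor mean RNA depth at untranscribed positions (mapping
#'   noise; keeps the expression background comparison non-degenerate).
#' @param error_rate per-read base error.
#' @param ase_fraction share of genes simulated cis-regulated.
#' @param afc_range range of |log2 allelic fold change| for cis genes.
#' @param tissues character vector of tissue names for the RNA assay.
#' @param tissue_cor correlation of per-gene log TPM between tissues.
#' @param homopolymer_rate injected homopolymer runs per kb of genome.
#' @param strand_bias_fraction fraction of sites given a biased alt-read
#'   strand ratio (exercises the FS filter).
#' @param strand_bias_p forward-strand probability of alt reads at biased
#'   sites.
#' @param gt_call_min_dp the simulated caller's minimum depth for emitting
#'   an individual genotype (below it the cell is "./.").
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_individuals = 15L,
                       n_genes = 30L,
                       exons_per_gene = c(2L, 6L),
                       exon_length = c(100L, 300L),
                       intron_length = c(300L, 700L),
                       intergenic_gap = c(1500L, 2500L),
                       prop_coding = 0.7,
                       maf_beta = c(0.5, 0.5),
                       site_density_kb = c(exonic = 5, intronic = 5,
                                           intergenic = 5),
                       dna_depth = 20,
                       rna_libsize_factor = 1,
                       tpm_meanlog = 2,
                       tpm_sdlog = 1.5,
                       intron_depth_fraction = 0.05,
                       noise_floor = 0.1,
                       error_rate = 0.005,
                       ase_fraction = 0.3,
                       afc_range = c(0.5, 3),
                       tissues = "liver",
                       tissue_cor = 0.8,
                       homopolymer_rate = 0.2,
                       strand_bias_fraction = 0.02,
                       strand_bias_p = 0.95,
                       gt_call_min_dp = 3L) {
  cfg <- as.list(environment())
  rates <- c(prop_coding = prop_coding, intron_depth_fraction = intron_depth_fraction,
             error_rate = error_rate, ase_fraction = ase_fraction,
             tissue_cor = tissue_cor, strand_bias_fraction = strand_bias_fraction,
             strand_bias_p = strand_bias_p)
  if (any(rates < 0 | rates > 1))
    stop("rate parameters must lie in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  if (dna_depth <= 0 || rna_libsize_factor <= 0)
    stop("depth parameters must be positive")
  if (any(maf_beta <= 0)) stop("maf_beta parameters must be positive")
  if (n_individuals < 1 || n_genes < 1)
    stop("n_individuals and n_genes must be >= 1")
  if (gt_call_min_dp < 0) stop("gt_call_min_dp must be >= 0")
  structure(cfg, class = "sim_config")
}

# Stage-specific deterministic seeds: each simulation stage reseeds from the
# config so stages can be re-run independently with identical output.
.stage_seed <- function(cfg, stage) {
  offsets <- c(genome = 101L, truth = 211L, coverage = 307L,
               callset = 401L, hapcounts = 503L, background = 601L)
  set.seed((cfg$seed %% 2147480000L) + offsets[[stage]])
}
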