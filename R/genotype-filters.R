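#' Genotype call rate (CR)
#'
#' Fraction of individuals with a called (non-missing) genotype at each
#' site. Report as a truncated integer percentage with [pct_trunc()] (1/6
#' renders as 16%).
#'
#' @param gt a `snp_callset` or a sites x samples dosage matrix.
#' @return numeric vector of per-site call rates in `[0, 1]`.
#' @export
call_rate <- function(gt) {
  gt <- .gt_matrix(gt)
  if (ncol(gt) == 0) stop("call rate needs at least one sample")
  rowMeans(!is.na(gt))
}

#' Depth-conditioned genotype call rate: (k.reads.DP) genotype CR
#'
#' Fraction of *all* individuals whose genotype is called and supported by
#' at least `k` reads. At `k = 0` this equals the plain call rate; it is
#' non-increasing in `k` and never exceeds the call rate. The all-samples
#' denominator is what makes this axis differ from CR in the selection
#' surface.
#'
#' @param cs a `snp_callset` (or a dosage matrix, with `dp` supplied).
#' @param k minimum reads per genotype.
#' @param dp depth matrix when `cs` is a plain matrix.
#' @return numeric vector of per-site rates in `[0, 1]`.
#' @export
dp_filtered_call_rate <- function(cs, k = 5, dp = NULL) {
  if (inherits(cs, "snp_callset")) { dp <- cs$dp; gt <- cs$gt } else gt <- cs
  if (k < 0) stop("k must be >= 0")
  if (ncol(gt) == 0) stop("call rate needs at least one sample")
  rowMeans(!is.na(gt) & !is.na(dp) & dp >= k)
}

#' Allele and genotype frequencies per site
#'
#' Computed over called genotypes only: `af = (n_het + 2 n_homalt) /
#' (2 n_called)`, `maf = min(af, 1 - af)`; genotype frequencies and the het
#' fraction share the called-only denominator. Sites with no called
#' genotype get NA and are flagged in the `undefined` column.
#'
#' @param gt a `snp_callset` or dosage matrix.
#' @return data.frame `af`, `maf`, `f_homref`, `f_het`, `f_homalt`,
#'   `het_fraction`, `n_called`, `undefined`.
#' @export
site_frequencies <- function(gt) {
  gt <- .gt_matrix(gt)
  n_called <- rowSums(!is.na(gt))
  n_het <- rowSums(gt == 1, na.rm = TRUE)
  n_alt <- rowSums(gt == 2, na.rm = TRUE)
  n_ref <- n_called - n_het - n_alt
  af <- ifelse(n_called > 0, (n_het + 2 * n_alt) / (2 * n_called), NA_real_)
  data.frame(af = af, maf = pmin(af, 1 - af),
             f_homref = n_ref / n_called, f_het = n_het / n_called,
             f_homalt = n_alt / n_called,
             het_fraction = n_het / n_called,
             n_called = n_called, undefined = n_called == 0)
}

#' Per-site genotype metrics table
#'
#' One row per site: call rate, the (k.reads.DP) call rate, summed
#' population depth, allele/genotype frequencies and the population het
#' prevalence (hets over all samples).
#'
#' @param cs a `snp_callset`.
#' @param k depth threshold for the conditioned call rate.
#' @return data.frame of metrics aligned with `cs$sites`.
#' @export
site_gt_metrics <- function(cs, k = 5) {
  fr <- site_frequencies(cs$gt)
  data.frame(cr = call_rate(cs$gt),
             dp_cr = dp_filtered_call_rate(cs, k),
             population_dp = rowSums(cs$dp, na.rm = TRUE),
             fr,
             het_prevalence = rowSums(cs$gt == 1, na.rm = TRUE) /
               ncol(cs$gt))
}

#' Select reliably genotyped sites
#'
#' The workflow's genotype selection: keep sites with
#' (k.reads.DP) genotype CR >= `dp_cr_min` AND CR >= `cr_min` (both
#' inclusive; defaults 20% and 50% with k = 5).
#'
#' @param cs a `snp_callset`.
#' @param k per-genotype depth threshold.
#' @param dp_cr_min minimum depth-conditioned call rate (fraction).
#' @param cr_min minimum call rate (fraction).
#' @return the selected `snp_callset`; the logical site index is in
#'   `attr(, "kept")`.
#' @export
select_genotyped_sites <- function(cs, k = 5, dp_cr_min = 0.20, cr_min = 0.50) {
  keep <- dp_filtered_call_rate(cs, k) >= dp_cr_min & call_rate(cs) >= cr_min
  out <- subset_sites(cs, keep)
  attr(out, "kept") <- keep
  out
}

#' Minor-allele-frequency filter
#'
#' Keeps sites whose MAF among called genotypes is at least `maf_min`
#' (inclusive; default 10%), discarding rare alleles and residual
#' sequencing-error sites.
#'
#' @param cs a `snp_callset`.
#' @param maf_min inclusive MAF threshold (fraction).
#' @return the filtered `snp_callset` with `attr(, "kept")`.
#' @export
maf_filter <- function(cs, maf_min = 0.10) {
  maf <- site_frequencies(cs$gt)$maf
  keep <- !is.na(maf) & maf >= maf_min
  out <- subset_sites(cs, keep)
  attr(out, "kept") <- keep
  out
}

#' Heterozygote-prevalence filter
#'
#' Keeps sites heterozygous in at least `min_het_frac` of the population
#' (denominator: all samples, called or not — "25% of the population" is
#' population-wide).
#'
#' @param cs a `snp_callset`.
#' @param min_het_frac inclusive het prevalence threshold (fraction).
#' @return the filtered `snp_callset` with `attr(, "kept")`.
#' @export
het_prevalence_filter <- function(cs, min_het_frac = 0.25) {
  prev <- rowSums(cs$gt == 1, na.rm = TRUE) / ncol(cs$gt)
  keep <- prev >= min_het_frac
  out <- subset_sites(cs, keep)
  attr(out, "kept") <- keep
  out
}

#' Truncated integer percentage
#'
#' Report-style rendering of a fraction: percentages are truncated toward
#' zero (1/6 -> 16), matching how call rates are quoted.
#'
#' @param x fractions in `[0, 1]`.
#' @return integer percentages.
#' @export
pct_trunc <- function(x) as.integer(floor(x * 100 + 1e-9))

.gt_matrix <- function(x) {
  if (inherits(x, "snp_callset")) x$gt else as.matrix(x)
}
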