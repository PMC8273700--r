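#' Keep biallelic SNP records
#'
#' Retains records with exactly one alternate allele where both ref and alt
#' are single bases (the `selectType SNP, restrictAllelesTo BIALLELIC`
#' selection every downstream stage assumes).
#'
#' @param cs a `snp_callset`.
#' @return the filtered `snp_callset`.
#' @export
select_biallelic_snps <- function(cs) {
  s <- cs$sites
  keep <- !grepl(",", s$alt, fixed = TRUE) &
    nchar(s$ref) == 1L & nchar(s$alt) == 1L &
    s$ref %in% c("A", "C", "G", "T") & s$alt %in% c("A", "C", "G", "T") &
    s$ref != s$alt
  subset_sites(cs, keep)
}

#' Phred-scaled Fisher strand bias (FS)
#'
#' Two-sided Fisher exact p-value of the 2x2 ref/alt x forward/reverse read
#' count table, reported as -10 log10(p). The two-sided p is the conditional
#' exact definition (sum of hypergeometric probabilities of all tables with
#' the observed margins whose probability does not exceed the observed
#' table's, with the customary 1e-7 relative tolerance for ties). Degenerate
#' tables (an empty row or column) have p = 1, hence FS = 0. p is floored at
#' 1e-300 before the phred transform.
#'
#' All four arguments are vectorised.
#'
#' @param ref_fwd,ref_rev,alt_fwd,alt_rev non-negative read counts.
#' @return numeric vector of FS values (>= 0).
#' @export
fisher_strand_phred <- function(ref_fwd, ref_rev, alt_fwd, alt_rev) {
  n <- max(length(ref_fwd), length(ref_rev), length(alt_fwd), length(alt_rev))
  a <- rep_len(ref_fwd, n); b <- rep_len(ref_rev, n)
  c_ <- rep_len(alt_fwd, n); d <- rep_len(alt_rev, n)
  if (any(c(a, b, c_, d) < 0)) stop("strand counts must be non-negative")
  p <- vapply(seq_len(n), function(i)
    .fisher2x2_p(a[i], b[i], c_[i], d[i]), numeric(1))
  -10 * log10(pmax(p, 1e-300))
}

# conditional two-sided exact p for one 2x2 table
.fisher2x2_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == r1 + r2) return(1)
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  x <- lo:hi
  pmf <- stats::dhyper(x, r1, r2, c1)
  obs <- pmf[x == a]
  min(1, sum(pmf[pmf <= obs * (1 + 1e-7)]))
}

#' Quality by depth (QD)
#'
#' Site confidence normalised by the informative read depth: `qual / depth`,
#' defined as 0 at zero depth.
#'
#' @param qual non-negative variant quality.
#' @param informative_depth non-negative read depth supporting the call.
#' @return numeric QD (vectorised).
#' @export
quality_by_depth <- function(qual, informative_depth) {
  if (any(qual < 0, na.rm = TRUE)) stop("qual must be non-negative")
  if (any(informative_depth < 0, na.rm = TRUE)) stop("depth must be non-negative")
  ifelse(informative_depth == 0, 0, qual / informative_depth)
}

#' Apply a hard-filter profile to a call set
#'
#' The `rna` profile fails a site iff QD < 2 or FS > 30 (the two
#' GATK-suggested RNA-seq filters retained by the workflow; the third,
#' SnpCluster, is a context *flag*, see [flag_snp_clusters()]). The `dna`
#' profile fails iff FS > 60, QD < 2, SOR > 3, MQ < 40, MQRankSum < -12.5 or
#' ReadPosRankSum < -8. Comparisons are strict as printed. Missing optional
#' statistics never fail a site (callers omit rank sums at many records);
#' missing QD/FS likewise pass, so pass-through records are not silently
#' dropped.
#'
#' @param cs a `snp_callset` with site statistics in `cs$sites`.
#' @param profile `"rna"` or `"dna"`.
#' @param strict if TRUE, drop failing sites; otherwise only label the
#'   FILTER column (`PASS` or the semicolon-joined failure labels).
#' @return the labelled (or filtered) `snp_callset`.
#' @export
apply_filter_profile <- function(cs, profile = c("rna", "dna"), strict = FALSE) {
  profile <- match.arg(profile)
  s <- cs$sites
  fails <- function(x, op, thr) !is.na(x) & op(x, thr)
  lab <- vector("list", nrow(s))
  add <- function(lab, idx, tag) { for (i in which(idx)) lab[[i]] <- c(lab[[i]], tag); lab }
  lab <- add(lab, fails(s$qd, `<`, 2), "QD2")
  if (profile == "rna") {
    lab <- add(lab, fails(s$fs, `>`, 30), "FS30")
  } else {
    lab <- add(lab, fails(s$fs, `>`, 60), "FS60")
    lab <- add(lab, fails(s$sor, `>`, 3), "SOR3")
    lab <- add(lab, fails(s$mq, `<`, 40), "MQ40")
    lab <- add(lab, fails(s$mq_rank_sum, `<`, -12.5), "MQRankSum-12.5")
    lab <- add(lab, fails(s$read_pos_rank_sum, `<`, -8), "ReadPosRankSum-8")
  }
  filt <- vapply(lab, function(x)
    if (is.null(x)) "PASS" else paste(x, collapse = ";"), "")
  cs$sites$filter <- filt
  if (strict) subset_sites(cs, filt == "PASS") else cs
}
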