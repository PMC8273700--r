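#' Multi-sample SNP call set
#'
#' The internal container behind every filtering and concordance stage: a
#' site table plus aligned sites x samples matrices of genotype dosage, read
#' depth and allele depths.
#'
#' Genotypes are stored as alt-allele dosage: 0 = hom-ref, 1 = het,
#' 2 = hom-alt, `NA` = uncalled ("./."). Site coordinates keep the 1-based
#' VCF `pos`; all interval arithmetic elsewhere uses 0-based half-open
#' coordinates (`pos - 1`).
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt` (comma-separated if multi-allelic), `qual`, `filter`, and
#'   optional site statistics `qd`, `fs`, `sor`, `mq`, `mq_rank_sum`,
#'   `read_pos_rank_sum` (NA when absent).
#' @param gt integer matrix of alt-allele dosages (0/1/2/NA).
#' @param dp integer matrix of per-genotype read depths.
#' @param ad_ref,ad_alt integer matrices of ref/alt allele depths (NA when
#'   the caller did not emit AD).
#' @param samples character vector of sample names (matrix columns).
#' @return An object of class `snp_callset`.
#' @export
snp_callset <- function(sites, gt, dp, ad_ref = NULL, ad_alt = NULL,
                        samples = colnames(gt)) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  n <- nrow(sites)
  gt <- as.matrix(gt); dp <- as.matrix(dp)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(gt)))
  if (nrow(gt) != n || nrow(dp) != n)
    stop("site table and matrices disagree on the number of sites")
  if (ncol(gt) != length(samples) || ncol(dp) != length(samples))
    stop("matrices disagree with the sample list")
  if (any(sites$pos < 1)) stop("VCF positions are 1-based; pos must be >= 1")
  if (is.null(ad_ref)) ad_ref <- matrix(NA_integer_, n, length(samples))
  if (is.null(ad_alt)) ad_alt <- matrix(NA_integer_, n, length(samples))
  for (col in c("id", "qual", "filter", "qd", "fs", "sor", "mq",
                "mq_rank_sum", "read_pos_rank_sum")) {
    if (is.null(sites[[col]])) {
      sites[[col]] <- rep(if (col %in% c("id", "filter")) NA_character_
                          else NA_real_, n)
    }
  }
  dimnames(gt) <- dimnames(dp) <- dimnames(ad_ref) <- dimnames(ad_alt) <-
    list(NULL, samples)
  structure(list(sites = sites, gt = gt, dp = dp,
                 ad_ref = ad_ref, ad_alt = ad_alt, samples = samples),
            class = "snp_callset")
}

#' @exportS3Method base::print
print.snp_callset <- function(x, ...) {
  cat(sprintf("<snp_callset> %d sites x %d samples\n",
              nrow(x$sites), length(x$samples)))
  cat(sprintf("  called genotypes: %.1f%%\n", 100 * mean(!is.na(x$gt))))
  invisible(x)
}

#' @export
dim.snp_callset <- function(x) c(nrow(x$sites), length(x$samples))

#' Subset a call set by site index
#'
#' @param cs a `snp_callset`.
#' @param i logical or integer site index.
#' @return The subset `snp_callset`.
#' @export
subset_sites <- function(cs, i) {
  snp_callset(cs$sites[i, , drop = FALSE],
              cs$gt[i, , drop = FALSE], cs$dp[i, , drop = FALSE],
              cs$ad_ref[i, , drop = FALSE], cs$ad_alt[i, , drop = FALSE],
              cs$samples)
}

#' Site identity keys
#'
#' Sites are identified by chromosome, position, ref and alt allele so that
#' call-set comparisons never credit a discordant alternate allele.
#'
#' @param cs a `snp_callset` (or its site table).
#' @return character vector of `chrom:pos:ref>alt` keys.
#' @export
site_keys <- function(cs) {
  s <- if (is.data.frame(cs)) cs else cs$sites
  if (nrow(s) == 0) return(character(0))
  paste0(s$chrom, ":", s$pos, ":", s$ref, ">", s$alt)
}
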