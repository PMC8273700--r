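#' Detection precision and recall between two call sets
#'
#' Sites are matched on (chrom, pos, ref, alt). Precision = fraction of
#' test-set sites confirmed by the reference; recall = fraction of
#' reference-set sites recovered. Optionally both sets are first restricted
#' to a region mask (e.g. expressed exons), the comparison the detection
#' benchmark uses.
#'
#' @param test,ref `snp_callset`s (or character key vectors from
#'   [site_keys()]).
#' @param mask optional data.frame of 0-based half-open intervals
#'   (`chrom`, `start`, `end`); only sites inside it are compared. Requires
#'   call sets (not bare keys).
#' @return list `precision`, `recall`, `n_test`, `n_ref`, `n_shared`;
#'   an empty test set yields NA precision with `undefined = TRUE`.
#' @export
detection_precision_recall <- function(test, ref, mask = NULL) {
  get_keys <- function(x) {
    if (is.character(x)) return(x)
    if (!is.null(mask)) x <- subset_sites(x, .in_mask(x$sites, mask))
    site_keys(x)
  }
  tk <- unique(get_keys(test)); rk <- unique(get_keys(ref))
  shared <- length(intersect(tk, rk))
  list(precision = if (length(tk)) shared / length(tk) else NA_real_,
       recall = if (length(rk)) shared / length(rk) else NA_real_,
       n_test = length(tk), n_ref = length(rk), n_shared = shared,
       undefined = length(tk) == 0)
}

.in_mask <- function(sites, mask) {
  pos0 <- sites$pos - 1L
  inside <- rep(FALSE, nrow(sites))
  for (i in seq_len(nrow(mask)))
    inside <- inside | (sites$chrom == mask$chrom[i] &
                          pos0 >= mask$start[i] & pos0 < mask$end[i])
  inside
}

#' Genotype concordance between two call sets
#'
#' Over shared sites (matched on chrom/pos/ref/alt) and shared samples:
#' restrict to test-set sites with call rate >= `cr_min`, then compare every
#' (site, sample) pair where both genotypes are called and the test depth is
#' >= `dp_min`. Reference genotypes are used unfiltered (the reference assay
#' is treated as truth).
#'
#' @param test,ref `snp_callset`s.
#' @param dp_min minimum test read depth per compared genotype.
#' @param cr_min minimum test call rate per compared site (fraction).
#' @return list `concordance` (percent), `n_compared`, `n_sites`;
#'   `concordance` is NA with `undefined = TRUE` when nothing is comparable.
#' @export
genotype_concordance <- function(test, ref, dp_min = 0, cr_min = 0) {
  m <- .match_callsets(test, ref)
  if (m$n == 0)
    return(list(concordance = NA_real_, n_compared = 0L, n_sites = 0L,
                undefined = TRUE))
  keep <- call_rate(m$test_gt) >= cr_min
  tg <- m$test_gt[keep, , drop = FALSE]
  td <- m$test_dp[keep, , drop = FALSE]
  rg <- m$ref_gt[keep, , drop = FALSE]
  cmp <- !is.na(tg) & !is.na(rg) & td >= dp_min
  n_cmp <- sum(cmp)
  list(concordance = if (n_cmp) 100 * sum(tg[cmp] == rg[cmp]) / n_cmp else NA_real_,
       n_compared = n_cmp, n_sites = sum(keep), undefined = n_cmp == 0)
}

.match_callsets <- function(test, ref) {
  samples <- intersect(test$samples, ref$samples)
  if (!length(samples)) stop("no shared samples between call sets")
  tk <- site_keys(test); rk <- site_keys(ref)
  idx <- match(tk, rk)
  sel <- !is.na(idx)
  list(n = sum(sel),
       test_gt = test$gt[sel, samples, drop = FALSE],
       test_dp = test$dp[sel, samples, drop = FALSE],
       ref_gt = ref$gt[idx[sel], samples, drop = FALSE],
       ref_dp = ref$dp[idx[sel], samples, drop = FALSE])
}

#' Concordance / retention selection surface
#'
#' For each grid cell (cr >= x, (k.reads.DP) CR >= y) reports the genotype
#' concordance over the >= k-read genotypes of the selected sites and the
#' percentage of test sites retained — the isocline surface behind the
#' chosen (20%, 50%) selection thresholds.
#'
#' @param test,ref `snp_callset`s.
#' @param cr_values,dp_cr_values ascending grids of thresholds (fractions).
#' @param k per-genotype depth behind the conditioned call rate.
#' @return data.frame `cr_min`, `dp_cr_min`, `concordance`, `retained_pct`,
#'   `n_sites`.
#' @export
concordance_grid <- function(test, ref, cr_values = seq(0, 1, 0.25),
                             dp_cr_values = seq(0, 1, 0.25), k = 5) {
  if (is.unsorted(cr_values) || is.unsorted(dp_cr_values))
    stop("grids must be ascending")
  m <- .match_callsets(test, ref)
  cr <- call_rate(test$gt)
  dpcr <- dp_filtered_call_rate(test, k)
  n_total <- nrow(test$sites)
  tk <- site_keys(test)
  sel_shared <- !is.na(match(tk, site_keys(ref)))
  out <- expand.grid(cr_min = cr_values, dp_cr_min = dp_cr_values,
                     KEEP.OUT.ATTRS = FALSE)
  out$concordance <- NA_real_; out$retained_pct <- NA_real_; out$n_sites <- 0L
  shared_rows <- which(sel_shared)
  for (i in seq_len(nrow(out))) {
    keep <- cr >= out$cr_min[i] & dpcr >= out$dp_cr_min[i]
    out$n_sites[i] <- sum(keep)
    out$retained_pct[i] <- 100 * sum(keep) / n_total
    krows <- which(keep[shared_rows])   # indices into matched matrices
    if (!length(krows)) next
    tg <- m$test_gt[krows, , drop = FALSE]
    td <- m$test_dp[krows, , drop = FALSE]
    rg <- m$ref_gt[krows, , drop = FALSE]
    cmp <- !is.na(tg) & !is.na(rg) & td >= k
    if (any(cmp))
      out$concordance[i] <- 100 * sum(tg[cmp] == rg[cmp]) / sum(cmp)
  }
  out
}

#' Merge per-tissue call sets into a consensus genotype matrix
#'
#' Sites are unioned across tissues. Per (site, sample): a genotype called
#' in a single tissue is kept; concordant multi-tissue calls are kept; a
#' discordant call takes the genotype of the tissue with the highest depth
#' (ties: the first tissue in input order, counted in
#' `attr(, "n_dp_ties")`). Pairwise inter-tissue genotype concordance is
#' reported overall and for genotypes supported by >= 5 and >= 10 reads in
#' both tissues.
#'
#' @param callsets named list of `snp_callset`s over the same samples.
#' @return the merged `snp_callset`, with attributes `concordance_report`
#'   (data.frame per tissue pair) and `n_dp_ties`.
#' @export
merge_tissues <- function(callsets) {
  stopifnot(length(callsets) >= 1)
  samples <- callsets[[1]]$samples
  for (cs in callsets)
    if (!identical(cs$samples, samples))
      stop("all tissues must share the same samples")
  keys <- unique(unlist(lapply(callsets, site_keys)))
  n <- length(keys); ns <- length(samples)

  gt <- matrix(NA_real_, n, ns, dimnames = list(NULL, samples))
  dp <- matrix(NA_real_, n, ns, dimnames = list(NULL, samples))
  ar <- matrix(NA_real_, n, ns); aa <- matrix(NA_real_, n, ns)
  ties <- 0L
  sites <- NULL
  site_filled <- rep(FALSE, n)
  for (t in seq_along(callsets)) {
    cs <- callsets[[t]]
    rows <- match(site_keys(cs), keys)
    if (is.null(sites)) {
      sites <- cs$sites[rep(1, n), , drop = FALSE]
      sites[] <- NA
    }
    new_rows <- !site_filled[rows]        # first tissue seen provides site meta
    sites[rows[new_rows], ] <- cs$sites[new_rows, , drop = FALSE]
    site_filled[rows] <- TRUE
    called <- !is.na(cs$gt)
    for (j in seq_len(ns)) {
      i_new <- rows[called[, j]]
      g_new <- cs$gt[called[, j], j]
      d_new <- cs$dp[called[, j], j]
      r_new <- cs$ad_ref[called[, j], j]; a_new <- cs$ad_alt[called[, j], j]
      prev <- !is.na(gt[i_new, j])
      # previously uncalled: take the new call
      take <- !prev
      # previously called and discordant: higher depth wins, tie -> keep first
      disc <- prev & gt[i_new, j] != g_new
      ties <- ties + sum(disc & d_new == dp[i_new, j], na.rm = TRUE)
      take <- take | (disc & d_new > dp[i_new, j])
      # concordant: keep genotype, record the larger depth
      conc <- prev & gt[i_new, j] == g_new
      upd_dp <- conc & d_new > dp[i_new, j]
      gt[i_new[take], j] <- g_new[take]
      dp[i_new[take | upd_dp], j] <- d_new[take | upd_dp]
      ar[i_new[take], j] <- r_new[take]; aa[i_new[take], j] <- a_new[take]
    }
  }
  # inter-tissue pairwise concordance report
  rep_rows <- list()
  if (length(callsets) >= 2) {
    nm <- names(callsets)
    if (is.null(nm)) nm <- paste0("tissue", seq_along(callsets))
    for (i in seq_along(callsets)) for (j in seq_along(callsets)) {
      if (j <= i) next
      m <- .match_callsets(callsets[[i]], callsets[[j]])
      if (m$n == 0) next
      for (dmin in c(0, 5, 10)) {
        cmp <- !is.na(m$test_gt) & !is.na(m$ref_gt) &
          m$test_dp >= dmin & m$ref_dp >= dmin
        rep_rows[[length(rep_rows) + 1]] <- data.frame(
          tissue_a = nm[i], tissue_b = nm[j], dp_min = dmin,
          n_compared = sum(cmp),
          concordance = if (any(cmp))
            100 * sum(m$test_gt[cmp] == m$ref_gt[cmp]) / sum(cmp)
          else NA_real_)
      }
    }
  }
  ord <- order(sites$chrom, sites$pos)
  out <- snp_callset(sites[ord, , drop = FALSE], gt[ord, , drop = FALSE],
                     dp[ord, , drop = FALSE], ar[ord, , drop = FALSE],
                     aa[ord, , drop = FALSE], samples)
  attr(out, "concordance_report") <-
    if (length(rep_rows)) do.call(rbind, rep_rows) else NULL
  attr(out, "n_dp_ties") <- ties
  out
}
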