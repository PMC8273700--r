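#' Cross-population union and intersection of SNP sets
#'
#' Sites are keyed by (chrom, pos, ref, alt). A population carries a site
#' iff the site is in its set (callers should pass the carried sites, i.e.
#' alt frequency > 0).
#'
#' @param site_sets named list of character key vectors (see [site_keys()]).
#' @return list `union`, `intersection` (counts), and the key vectors
#'   `union_keys`, `intersection_keys`.
#' @export
cross_population_sets <- function(site_sets) {
  sets <- lapply(site_sets, unique)
  u <- Reduce(union, sets)
  i <- Reduce(intersect, sets)
  list(union = length(u), intersection = length(i),
       union_keys = u, intersection_keys = i)
}

#' Tiered per-population SNP accounting table
#'
#' Reproduces the arithmetic of the per-population accounting: per
#' population the SNP totals, selected-genotype counts and MAF-selected
#' counts for a single tissue and for the multi-tissue union, the
#' multi/single and tier ratios (2 decimals), and a Mean row (counts
#' rounded to integers, ratios the 2-decimal mean of the column). Missing
#' cells (a population without the single tissue) are skipped in the means.
#'
#' @param counts data.frame with columns `population`, `single_total`,
#'   `multi_total`, `single_gt`, `multi_gt`, `single_maf`, `multi_maf`
#'   (NA allowed).
#' @return data.frame with ratio columns and a final `"Mean"` row.
#' @export
population_summary_table <- function(counts) {
  x <- counts
  r2 <- function(v) round(v, 2)
  x$ratio_total <- r2(x$multi_total / x$single_total)
  x$ratio_gt <- r2(x$multi_gt / x$single_gt)
  x$gt_over_total_single <- r2(x$single_gt / x$single_total)
  x$gt_over_total_multi <- r2(x$multi_gt / x$multi_total)
  x$ratio_maf <- r2(x$multi_maf / x$single_maf)
  x$maf_over_total_single <- r2(x$single_maf / x$single_total)
  x$maf_over_total_multi <- r2(x$multi_maf / x$multi_total)
  mean_row <- x[1, ]
  mean_row$population <- "Mean"
  for (col in names(x)[-1]) {
    v <- x[[col]][!is.na(x[[col]])]
    mean_row[[col]] <- if (grepl("^ratio|over_total", col)) r2(mean(v))
                       else round(mean(v))
  }
  rbind(x, mean_row)
}

#' Consequence-severity accounting
#'
#' Counts variant-effect predictions per category; the severe total sums
#' stop_gained, splice_site, deleterious_missense and start_or_stop_lost.
#' Unknown categories are counted under `other` with a warning.
#'
#' @param categories character vector (one prediction per element) or a
#'   named count vector.
#' @return list `counts` (named), `severe_total`, `grand_total`.
#' @export
consequence_summary <- function(categories) {
  known <- c("stop_gained", "splice_site", "deleterious_missense",
             "start_or_stop_lost", "tolerated_missense", "synonymous", "other")
  if (is.numeric(categories)) {
    cnt <- categories
  } else {
    cnt <- table(categories)
  }
  unknown <- setdiff(names(cnt), known)
  if (length(unknown)) {
    warning("unknown consequence categories counted as 'other': ",
            paste(unknown, collapse = ", "))
    cnt["other"] <- sum(cnt[unknown]) +
      if ("other" %in% names(cnt)) cnt[["other"]] else 0
    cnt <- cnt[!names(cnt) %in% unknown]
  }
  out <- stats::setNames(rep(0, length(known)), known)
  out[names(cnt)] <- as.numeric(cnt)
  severe <- sum(out[c("stop_gained", "splice_site", "deleterious_missense",
                      "start_or_stop_lost")])
  list(counts = out, severe_total = severe, grand_total = sum(out))
}

#' ALT/ALT genotype frequency profile
#'
#' Classifies each variant by its homozygous-alt frequency across the
#' populations that carry the alt allele: `altalt_absent` (frequency 0 in
#' every carrying population), `altalt_le` (maximum frequency <= `threshold`
#' but not absent), else `other`. Variants carried nowhere are excluded and
#' counted.
#'
#' @param homalt_freq matrix variants x populations of hom-alt genotype
#'   frequencies.
#' @param af matrix of the same shape with alt allele frequencies.
#' @param threshold the low-frequency bound (default 0.05).
#' @return list `class` (per variant), `pct_absent`, `pct_low` (nearest
#'   integer percentages; `pct_low` includes absent variants, i.e. max
#'   hom-alt frequency <= threshold), `n_excluded`.
#' @export
altalt_profile <- function(homalt_freq, af, threshold = 0.05) {
  homalt_freq <- as.matrix(homalt_freq); af <- as.matrix(af)
  carried <- af > 0
  n_carry <- rowSums(carried, na.rm = TRUE)
  excl <- n_carry == 0
  max_fa <- rep(NA_real_, nrow(af))
  hf <- homalt_freq; hf[!carried] <- NA
  max_fa[!excl] <- apply(hf[!excl, , drop = FALSE], 1, max, na.rm = TRUE)
  cls <- rep(NA_character_, nrow(af))
  cls[!excl & max_fa == 0] <- "altalt_absent"
  cls[!excl & max_fa > 0 & max_fa <= threshold] <- "altalt_le"
  cls[!excl & max_fa > threshold] <- "other"
  n <- sum(!excl)
  list(class = cls,
       pct_absent = report_pct(sum(cls == "altalt_absent", na.rm = TRUE), n),
       pct_low = report_pct(sum(cls %in% c("altalt_absent", "altalt_le"),
                                na.rm = TRUE), n),
       n_excluded = sum(excl))
}

#' Nearest-integer percentage for reporting
#'
#' @param count,total non-negative numbers.
#' @return `round(100 * count / total)`.
#' @export
report_pct <- function(count, total) round(100 * count / total)

#' Identity-by-state distance matrix
#'
#' IBS(i, j) = mean over sites called in both individuals of
#' `(2 - |dosage_i - dosage_j|) / 2`; distance = 1 - IBS. A pair with no
#' shared called site is an error.
#'
#' @param gt dosage matrix, sites x individuals (NA = missing).
#' @return symmetric distance matrix with zero diagonal.
#' @export
ibs_distance <- function(gt) {
  gt <- as.matrix(gt)
  n <- ncol(gt)
  labs <- colnames(gt)
  if (is.null(labs)) labs <- paste0("ind", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(gt[, i]) & !is.na(gt[, j])
    if (!any(ok))
      stop(sprintf("no shared called sites between %s and %s",
                   labs[i], labs[j]))
    ibs <- mean((2 - abs(gt[ok, i] - gt[ok, j])) / 2)
    d[i, j] <- d[j, i] <- 1 - ibs
  }
  d
}

#' IBS hierarchical clustering
#'
#' Average-linkage agglomeration on the IBS distance; ties are resolved
#' deterministically by label order (stats::hclust is deterministic given
#' the matrix).
#'
#' @param gt dosage matrix, sites x individuals.
#' @return list `dist` (matrix), `hclust`, `phylo` (ape), `newick` (string).
#' @export
ibs_cluster <- function(gt) {
  d <- ibs_distance(gt)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ph <- ape::as.phylo(hc)
  list(dist = d, hclust = hc, phylo = ph,
       newick = ape::write.tree(ph))
}
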