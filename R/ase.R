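#' ASE-eligible gene tiers
#'
#' Counts, per biotype, the genes that can be analysed for allele-specific
#' expression at three nested tiers: tier 1 = expressed genes
#' (TPM >= `tpm_min`) with at least one reliably genotyped SNP in the chosen
#' region; tier 2 = tier 1 restricted to SNPs with MAF >= 10%; tier 3 =
#' tier 2 restricted to SNPs heterozygous in >= 25% of the population.
#' `s_per_g` is the mean number of qualifying SNPs per qualifying gene at
#' each tier.
#'
#' @param gene_expr data.frame `gene_id`, `biotype`, `tpm`.
#' @param site_table data.frame with one row per SNP: `gene_id`, `region`
#'   (`"exon"` or `"intron"`), and logicals `gt_selected`, `maf_ok`,
#'   `het_ok`.
#' @param tpm_min expression threshold (0.1 or 1 in practice).
#' @param region `"exons"` or `"exons_introns"`.
#' @return data.frame `tier`, `biotype`, `n_genes`, `s_per_g`.
#' @export
ase_eligible_genes <- function(gene_expr, site_table,
                               tpm_min = 1,
                               region = c("exons", "exons_introns")) {
  region <- match.arg(region)
  st <- site_table[!is.na(site_table$gene_id), , drop = FALSE]
  if (region == "exons") st <- st[st$region == "exon", , drop = FALSE]
  expressed <- gene_expr[gene_expr$tpm >= tpm_min &
                           gene_expr$biotype %in% c("protein_coding", "lncRNA"), ]
  qual <- list(tier1 = st$gt_selected,
               tier2 = st$gt_selected & st$maf_ok,
               tier3 = st$gt_selected & st$maf_ok & st$het_ok)
  out <- list()
  for (tier in names(qual)) {
    sub <- st[qual[[tier]], , drop = FALSE]
    cnt <- table(sub$gene_id)
    for (bt in c("protein_coding", "lncRNA")) {
      genes_bt <- expressed$gene_id[expressed$biotype == bt]
      hit <- intersect(names(cnt), genes_bt)
      out[[length(out) + 1]] <- data.frame(
        tier = tier, biotype = bt, n_genes = length(hit),
        n_expressed = length(genes_bt),
        s_per_g = if (length(hit)) mean(as.numeric(cnt[hit])) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Aggregate phased per-SNP counts into gene haplotype counts
#'
#' Selects one haplotype block per gene and sample — the block covering the
#' most SNPs, ties broken by total reads, then by leftmost coordinate — and
#' sums reads per phase across its SNPs into the two "super-allele" counts.
#'
#' @param snp_counts data.frame with `gene_id`, `sample`, `block`, `pos`,
#'   `hapA`, `hapB` (per-SNP phased read counts).
#' @return data.frame `gene_id`, `sample`, `count_hapA`, `count_hapB`,
#'   `n_snps_in_haplotype`. Gene/sample pairs with no phased SNPs are absent
#'   (skipped), their number is in `attr(, "n_skipped")`.
#' @export
aggregate_haplotype_counts <- function(snp_counts) {
  sp <- split(snp_counts, list(snp_counts$gene_id, snp_counts$sample),
              drop = TRUE)
  rows <- lapply(sp, function(d) {
    bl <- split(d, d$block)
    n_snps <- vapply(bl, nrow, integer(1))
    reads <- vapply(bl, function(b) sum(b$hapA + b$hapB), numeric(1))
    first <- vapply(bl, function(b) min(b$pos), numeric(1))
    pick <- order(-n_snps, -reads, first)[1]
    b <- bl[[pick]]
    data.frame(gene_id = d$gene_id[1], sample = d$sample[1],
               count_hapA = sum(b$hapA), count_hapB = sum(b$hapB),
               n_snps_in_haplotype = nrow(b), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exact binomial test for allelic imbalance
#'
#' Two-sided exact binomial p-value for `count_hapA` successes out of
#' `count_hapA + count_hapB` trials under the null of equal expression of
#' the two super-alleles (p = 0.5). Vectorised.
#'
#' @param count_hapA,count_hapB non-negative read counts.
#' @return numeric p-values; NA where both counts are 0.
#' @export
binomial_ase_test <- function(count_hapA, count_hapB) {
  n <- count_hapA + count_hapB
  mapply(function(a, tot) {
    if (tot == 0) return(NA_real_)
    stats::binom.test(a, tot, 0.5)$p.value
  }, count_hapA, n)
}

#' Benjamini-Hochberg adjustment with a rejection set
#'
#' Standard step-up BH at the given FDR.
#'
#' @param p numeric p-values in `[0, 1]` (NA allowed, never rejected).
#' @param fdr target false discovery rate.
#' @return list `q` (adjusted values) and `reject` (logical).
#' @export
bh_adjust <- function(p, fdr = 0.05) {
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = !is.na(q) & q <= fdr)
}

#' Call ASE genes from haplotype count tables
#'
#' Per sample, tests every eligible gene (at least `min_reads` reads on the
#' larger super-allele by default, or on the total with
#' `min_reads_mode = "total"`) with the exact binomial test, adjusts
#' p-values per sample across genes (BH), and calls a gene ASE iff it is
#' significant (q <= `fdr`) in at least `min_samples` samples. The reported
#' |log2 aFC| uses a 0.5 pseudocount on both counts; the test itself uses
#' raw counts.
#'
#' @param counts data.frame `gene_id`, `sample`, `count_hapA`,
#'   `count_hapB`.
#' @param fdr per-sample BH false discovery rate.
#' @param min_reads eligibility threshold in reads.
#' @param min_samples minimum significant samples for an ASE call.
#' @param min_reads_mode `"max"` (>= min_reads on one super-allele, the
#'   literal rule) or `"total"`.
#' @return list `per_sample` (tested rows with `p`, `q`, `significant`,
#'   `abs_log2_afc`) and `genes` (`gene_id`, `n_tested_samples`,
#'   `n_significant_samples`, `median_abs_log2_afc`, `is_ase`).
#' @export
call_ase_genes <- function(counts, fdr = 0.05, min_reads = 10,
                           min_samples = 2,
                           min_reads_mode = c("max", "total")) {
  min_reads_mode <- match.arg(min_reads_mode)
  elig <- if (min_reads_mode == "max")
    pmax(counts$count_hapA, counts$count_hapB) >= min_reads
  else counts$count_hapA + counts$count_hapB >= min_reads
  tested <- counts[elig, , drop = FALSE]
  if (!nrow(tested))
    return(list(per_sample = cbind(tested, p = numeric(0), q = numeric(0),
                                   significant = logical(0),
                                   abs_log2_afc = numeric(0)),
                genes = data.frame(gene_id = character(),
                                   n_tested_samples = integer(),
                                   n_significant_samples = integer(),
                                   median_abs_log2_afc = numeric(),
                                   is_ase = logical())))
  tested$p <- binomial_ase_test(tested$count_hapA, tested$count_hapB)
  tested$q <- NA_real_
  for (s in unique(tested$sample)) {      # BH per sample across genes
    i <- tested$sample == s
    tested$q[i] <- stats::p.adjust(tested$p[i], method = "BH")
  }
  tested$significant <- !is.na(tested$q) & tested$q <= fdr
  tested$abs_log2_afc <- abs(log2((tested$count_hapA + 0.5) /
                                    (tested$count_hapB + 0.5)))
  agg <- split(tested, tested$gene_id)
  genes <- do.call(rbind, lapply(agg, function(d)
    data.frame(gene_id = d$gene_id[1],
               n_tested_samples = nrow(d),
               n_significant_samples = sum(d$significant),
               median_abs_log2_afc = stats::median(d$abs_log2_afc),
               stringsAsFactors = FALSE)))
  genes$is_ase <- genes$n_significant_samples >= min_samples
  rownames(genes) <- NULL
  list(per_sample = tested, genes = genes)
}

#' Cross-population ASE summary
#'
#' Fractions of testable expressed genes called ASE per population and the
#' sizes of every intersection of the populations' ASE gene sets.
#'
#' @param results named list of `genes` data.frames from
#'   [call_ase_genes()].
#' @return list `per_population` (data.frame `population`, `n_testable`,
#'   `n_ase`, `fraction_ase`) and `shared` (named intersection counts; for
#'   two populations: `n_shared` plus each set size).
#' @export
population_ase_summary <- function(results) {
  per_pop <- do.call(rbind, lapply(names(results), function(nm) {
    g <- results[[nm]]
    data.frame(population = nm, n_testable = nrow(g), n_ase = sum(g$is_ase),
               fraction_ase = if (nrow(g)) mean(g$is_ase) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  sets <- lapply(results, function(g) g$gene_id[g$is_ase])
  shared <- length(Reduce(intersect, sets))
  list(per_population = per_pop,
       shared = c(n_shared_all = shared,
                  stats::setNames(lengths(sets), paste0("n_", names(sets)))))
}
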