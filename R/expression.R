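#' Exon expression score: reads per kilobase (RpKb)
#'
#' RpKb = mean mapped read count across samples divided by exon length in
#' kilobases; the working score is `log10(RpKb + 1)`.
#'
#' @param counts matrix or data.frame of read counts, exons x samples.
#' @param lengths exon lengths in bp, aligned with the rows of `counts`.
#' @param exon_id optional exon identifiers.
#' @return data.frame `exon_id`, `length`, `mean_reads`, `rpkb`,
#'   `log_score`.
#' @export
compute_rpkb <- function(counts, lengths, exon_id = NULL) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("exon lengths must be positive")
  if (nrow(counts) != length(lengths))
    stop("counts rows and lengths differ")
  if (any(counts < 0)) stop("read counts must be non-negative")
  if (is.null(exon_id)) exon_id <- rownames(counts)
  if (is.null(exon_id)) exon_id <- paste0("exon", seq_along(lengths))
  mean_reads <- rowMeans(counts)
  rpkb <- mean_reads / (lengths / 1000)
  data.frame(exon_id = exon_id, length = lengths, mean_reads = mean_reads,
             rpkb = rpkb, log_score = log10(rpkb + 1),
             stringsAsFactors = FALSE)
}

#' Generate background loci away from transcribed regions
#'
#' Places `n` intervals with lengths drawn from `length_pool` uniformly on
#' the genome, rejecting any placement closer than `min_dist` bases to a
#' transcribed (gene body) interval — the shuffled-loci background whose
#' expression justifies the exon threshold.
#'
#' @param models a [gene_models()]; gene bodies define transcribed space.
#' @param genome_lengths named vector of chromosome lengths.
#' @param n number of loci.
#' @param length_pool lengths (bp) to sample from, e.g. the lncRNA length
#'   distribution.
#' @param min_dist minimum distance to any transcribed interval.
#' @param max_tries rejection-sampling cap per locus.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open).
#' @export
generate_background_loci <- function(models, genome_lengths, n, length_pool,
                                     min_dist = 5000, max_tries = 1000) {
  g <- models$genes
  out <- vector("list", n)
  chroms <- names(genome_lengths)
  for (i in seq_len(n)) {
    len <- sample(length_pool, 1)
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cc <- sample(chroms, 1, prob = genome_lengths / sum(genome_lengths))
      if (genome_lengths[[cc]] <= len) next
      start <- sample.int(genome_lengths[[cc]] - len, 1) - 1L
      end <- start + len
      gg <- g[g$chrom == cc, , drop = FALSE]
      clash <- any(start < gg$end + min_dist & end > gg$start - min_dist)
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf(paste0("could not place background locus %d (length %d)",
                          " after %d tries; %d transcribed intervals,",
                          " min_dist = %d"),
                   i, len, max_tries, nrow(g), min_dist))
    out[[i]] <- data.frame(chrom = cc, start = start, end = end,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Select expressed exons by log RpKb threshold
#'
#' Keeps exons with `log10(RpKb + 1) >= threshold` (inclusive; default 0.5).
#' The first quartile of the exon score distribution (type-7 quantile) and,
#' when given, the background score distribution are reported so the
#' threshold choice is auditable.
#'
#' @param expr data.frame from [compute_rpkb()].
#' @param threshold inclusive `log_score` threshold.
#' @param background_scores optional numeric `log_score`s of background
#'   loci.
#' @return list `expressed` (the kept rows), `kept` (logical),
#'   `first_quartile`, `background_median`.
#' @export
select_expressed_exons <- function(expr, threshold = 0.5,
                                   background_scores = NULL) {
  kept <- expr$log_score >= threshold
  list(expressed = expr[kept, , drop = FALSE], kept = kept,
       first_quartile = unname(stats::quantile(expr$log_score, 0.25, type = 7)),
       background_median = if (is.null(background_scores)) NA_real_
       else stats::median(background_scores))
}

#' Simulate exon and background read counts
#'
#' Exon counts per sample are Poisson with mean
#' `rna_libsize_factor x TPM x length_kb`; background locus counts use the
#' mapping-noise floor per kb. Complements the site-level coverage model for
#' the expression-threshold stage.
#'
#' @param cfg a [sim_config()].
#' @param truth a `sim_truth`.
#' @param models a [gene_models()].
#' @param background optional data.frame of background loci intervals.
#' @param tissue tissue driving the TPM.
#' @return list `exon_counts` (matrix), `exon_lengths`, `exon_id`,
#'   `exon_gene`, and when `background` is given `bg_counts`, `bg_lengths`.
#' @export
simulate_exon_counts <- function(cfg, truth, models, background = NULL,
                                 tissue = cfg$tissues[1]) {
  .stage_seed(cfg, "background")
  ex <- models$features[models$features$type == "exon", , drop = FALSE]
  len <- ex$end - ex$start
  tpm <- truth$tpm[match(ex$gene_id, rownames(truth$tpm)),
                   match(tissue, cfg$tissues)]
  n <- length(truth$samples)
  mean_reads <- cfg$rna_libsize_factor * tpm * len / 1000
  counts <- matrix(stats::rpois(length(len) * n, rep(mean_reads, n)),
                   length(len), n, dimnames = list(NULL, truth$samples))
  out <- list(exon_counts = counts, exon_lengths = len,
              exon_id = paste0(ex$gene_id, "_e", stats::ave(ex$start, ex$gene_id,
                                                            FUN = seq_along)),
              exon_gene = ex$gene_id)
  if (!is.null(background)) {
    blen <- background$end - background$start
    bmean <- cfg$noise_floor * blen / 1000
    out$bg_counts <- matrix(stats::rpois(length(blen) * n, rep(bmean, n)),
                            length(blen), n)
    out$bg_lengths <- blen
  }
  out
}
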