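#' Flag SNP clusters (>= min_snps SNPs in a sliding window)
#'
#' A SNP is flagged iff some window of `window` consecutive bases containing
#' it holds at least `min_snps` SNPs (default: 3 SNPs in 35 bp, the
#' GATK-suggested RNA-seq criterion). Clusters are flagged, never removed:
#' the filter would discard too many true SNPs for the precision it buys.
#'
#' @param positions sorted numeric positions on one chromosome (any
#'   consistent coordinate convention).
#' @param window window width in bases.
#' @param min_snps minimum SNPs per qualifying window.
#' @return logical vector aligned with `positions`.
#' @export
flag_snp_clusters <- function(positions, window = 35, min_snps = 3) {
  n <- length(positions)
  if (is.unsorted(positions)) stop("positions must be sorted")
  flag <- rep(FALSE, n)
  if (n < min_snps) return(flag)
  w <- window - 1
  # every run of min_snps consecutive SNPs with span <= w qualifies; it flags
  # all SNPs coverable by a window containing the run
  for (j in seq_len(n - min_snps + 1)) {
    hi <- j + min_snps - 1
    if (positions[hi] - positions[j] <= w)
      flag <- flag | (positions >= positions[hi] - w &
                        positions <= positions[j] + w)
  }
  flag
}

#' Find homopolymer runs
#'
#' Maximal runs of one repeated base with length >= `min_len` (default 5).
#'
#' @param sequence one uppercase DNA string.
#' @param min_len minimum run length.
#' @return data.frame `start`, `end` (0-based half-open), `base`.
#' @export
find_homopolymers <- function(sequence, min_len = 5) {
  r <- rle(strsplit(sequence, "")[[1]])
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_len & r$values %in% c("A", "C", "G", "T")
  data.frame(start = (ends - r$lengths)[keep], end = ends[keep],
             base = r$values[keep], stringsAsFactors = FALSE)
}

#' Flag SNPs inside homopolymer runs
#'
#' A SNP is flagged iff its position lies inside a run interval (inclusive
#' of the first base). Positions adjacent to, but outside, a run are not
#' flagged unless `pad > 0` extends the intervals.
#'
#' @param pos0 0-based SNP positions.
#' @param runs data.frame from [find_homopolymers()].
#' @param pad bases by which to extend each run on both sides.
#' @return logical vector aligned with `pos0`.
#' @export
flag_homopolymer <- function(pos0, runs, pad = 0) {
  if (!nrow(runs)) return(rep(FALSE, length(pos0)))
  flag <- rep(FALSE, length(pos0))
  for (i in seq_len(nrow(runs)))
    flag <- flag | (pos0 >= runs$start[i] - pad & pos0 < runs$end[i] + pad)
  flag
}

#' Flag SNPs near exon-exon junctions
#'
#' Flags SNPs within `dist` exonic bases of a splice boundary: among the
#' last `dist` bases of the upstream exon or the first `dist` bases of the
#' downstream exon. Intronic positions are never flagged — the concern is
#' exonic mapping errors near splice sites.
#'
#' @param pos0 0-based SNP positions.
#' @param junctions data.frame from [gene_junctions()] (`donor_end`,
#'   `acceptor_start`).
#' @param dist flank width in bases.
#' @return logical vector aligned with `pos0`.
#' @export
flag_junction_proximity <- function(pos0, junctions, dist = 5) {
  flag <- rep(FALSE, length(pos0))
  for (i in seq_len(nrow(junctions))) {
    de <- junctions$donor_end[i]; as_ <- junctions$acceptor_start[i]
    flag <- flag | (pos0 >= de - dist & pos0 < de) |
      (pos0 >= as_ & pos0 < as_ + dist)
  }
  flag
}

#' Classify SNPs by genomic feature
#'
#' Assigns each SNP exactly one class with precedence
#' CDS > UTR5 > UTR3 > exon_noncoding > intron > intergenic when it overlaps
#' several genes or transcript parts.
#'
#' @param chrom,pos0 SNP coordinates (0-based).
#' @param models a [gene_models()].
#' @return character vector of feature classes.
#' @export
classify_feature <- function(chrom, pos0, models) {
  n <- length(pos0)
  cls <- rep("intergenic", n)
  hit <- function(iv) {
    h <- rep(FALSE, n)
    for (cc in unique(iv$chrom)) {
      sel <- iv$chrom == cc
      ir <- IRanges::IRanges(iv$start[sel] + 1L, iv$end[sel])  # 1-based closed
      q <- IRanges::IRanges(pos0 + 1L, pos0 + 1L)
      h <- h | (chrom == cc &
                  IRanges::overlapsAny(q, ir))
    }
    h
  }
  g <- models$genes
  in_gene <- hit(g)
  cls[in_gene] <- "intron"
  f <- models$features
  ex <- f[f$type == "exon", ]
  in_exon <- hit(ex)
  cls[in_exon] <- "exon_noncoding"
  for (ty in c("UTR3", "UTR5", "CDS")) {        # ascending precedence
    sub <- f[f$type == ty, ]
    if (nrow(sub)) cls[hit(sub)] <- ty
  }
  cls
}

#' Annotate a call set with context flags
#'
#' Adds `in_cluster`, `in_homopolymer`, `near_junction` and `feature_class`
#' columns to the site table.
#'
#' @param cs a `snp_callset`.
#' @param models a [gene_models()].
#' @param genome named character vector of reference sequences.
#' @param window,min_snps cluster parameters.
#' @param hp_min_len homopolymer minimum run length.
#' @param junction_dist junction flank width.
#' @return `cs` with the four context columns filled in.
#' @export
annotate_context <- function(cs, models, genome, window = 35, min_snps = 3,
                             hp_min_len = 5, junction_dist = 5) {
  s <- cs$sites
  pos0 <- s$pos - 1L
  s$in_cluster <- FALSE; s$in_homopolymer <- FALSE; s$near_junction <- FALSE
  junc <- gene_junctions(models)
  for (cc in unique(s$chrom)) {
    sel <- which(s$chrom == cc)
    sel <- sel[order(pos0[sel])]
    s$in_cluster[sel] <- flag_snp_clusters(pos0[sel], window, min_snps)
    if (cc %in% names(genome)) {
      runs <- find_homopolymers(genome[[cc]], hp_min_len)
      s$in_homopolymer[s$chrom == cc] <-
        flag_homopolymer(pos0[s$chrom == cc], runs)
    }
    jc <- junc[junc$chrom == cc, , drop = FALSE]
    s$near_junction[s$chrom == cc] <-
      flag_junction_proximity(pos0[s$chrom == cc], jc, junction_dist)
  }
  s$feature_class <- classify_feature(s$chrom, pos0, models)
  cs$sites <- s
  cs
}

#' Flag prevalence enrichment between two SNP sets
#'
#' Ratio of flag prevalences between set A and set B with a Pearson
#' chi-square test (2x2, no continuity correction — the compared counts are
#' large in practice).
#'
#' @param flagged_a,n_a flagged count and total in set A.
#' @param flagged_b,n_b flagged count and total in set B.
#' @return list `ratio`, `prevalence_a`, `prevalence_b`, `p_value`.
#' @export
flag_enrichment <- function(flagged_a, n_a, flagged_b, n_b) {
  if (n_a == 0) stop("set A is empty")
  if (n_b == 0) stop("set B is empty")
  pa <- flagged_a / n_a; pb <- flagged_b / n_b
  tab <- matrix(c(flagged_a, n_a - flagged_a, flagged_b, n_b - flagged_b), 2)
  p <- if (pb == 0 && pa == 0) 1 else
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  list(ratio = if (pb > 0) pa / pb else NA_real_,
       prevalence_a = pa, prevalence_b = pb, p_value = p)
}
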