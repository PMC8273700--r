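#' Build a toy genome with gene structure
#'
#' Lays `n_genes` genes along one chromosome, alternating exons and introns
#' and separated by intergenic gaps, over a random base sequence into which
#' homopolymer runs (length 5-8) are injected at the configured per-kb rate.
#' Protein-coding genes get UTR5/CDS/UTR3 sub-features; lncRNA genes carry
#' exons only.
#'
#' @param cfg a [sim_config()].
#' @return list with `genome` (named character vector of sequences),
#'   `models` (a [gene_models()]), and `homopolymers` (data.frame of the
#'   injected run intervals, 0-based half-open).
#' @export
build_toy_genome <- function(cfg) {
  .stage_seed(cfg, "genome")
  chrom <- "chr1"
  genes <- list(); feats <- list()
  pos <- 0L
  runif_int <- function(rng) {
    x <- seq(rng[1], rng[2])
    x[sample.int(length(x), 1L)]
  }
  for (g in seq_len(cfg$n_genes)) {
    pos <- pos + runif_int(cfg$intergenic_gap)
    n_ex <- runif_int(cfg$exons_per_gene)
    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    p <- pos
    for (e in seq_len(n_ex)) {
      ex_start[e] <- p
      p <- p + runif_int(cfg$exon_length)
      ex_end[e] <- p
      if (e < n_ex) p <- p + runif_int(cfg$intron_length)
    }
    gid <- sprintf("G%03d", g)
    biotype <- if (stats::runif(1) < cfg$prop_coding) "protein_coding" else "lncRNA"
    genes[[g]] <- data.frame(gene_id = gid, biotype = biotype, chrom = chrom,
                             start = pos, end = p, strand = "+",
                             stringsAsFactors = FALSE)
    f <- data.frame(gene_id = gid, type = "exon", chrom = chrom,
                    start = ex_start, end = ex_end, stringsAsFactors = FALSE)
    if (biotype == "protein_coding") {
      # UTR5 = first 30 bp of the first exon, UTR3 = last 60 bp of the last
      # exon, CDS = the remaining exonic sequence
      u5 <- c(ex_start[1], min(ex_start[1] + 30L, ex_end[1]))
      u3 <- c(max(ex_end[n_ex] - 60L, ex_start[n_ex]), ex_end[n_ex])
      cds_s <- ex_start; cds_e <- ex_end
      cds_s[1] <- u5[2]; cds_e[n_ex] <- u3[1]
      keep <- cds_s < cds_e
      f <- rbind(f,
                 data.frame(gene_id = gid, type = "UTR5", chrom = chrom,
                            start = u5[1], end = u5[2], stringsAsFactors = FALSE),
                 data.frame(gene_id = gid, type = "UTR3", chrom = chrom,
                            start = u3[1], end = u3[2], stringsAsFactors = FALSE),
                 data.frame(gene_id = gid, type = "CDS", chrom = chrom,
                            start = cds_s[keep], end = cds_e[keep],
                            stringsAsFactors = FALSE))
    }
    feats[[g]] <- f
    pos <- p
  }
  total_len <- pos + runif_int(cfg$intergenic_gap)
  models <- gene_models(do.call(rbind, genes), do.call(rbind, feats))

  seq_chars <- sample(c("A", "C", "G", "T"), total_len, replace = TRUE)
  n_runs <- stats::rpois(1, cfg$homopolymer_rate * total_len / 1000)
  hp <- data.frame(chrom = character(), start = integer(), end = integer(),
                   base = character(), stringsAsFactors = FALSE)
  if (n_runs > 0) {
    lens <- sample(5:8, n_runs, replace = TRUE)
    starts <- sort(sample.int(total_len - 10L, n_runs))
    bases <- sample(c("A", "C", "G", "T"), n_runs, replace = TRUE)
    for (i in seq_len(n_runs))
      seq_chars[(starts[i] + 1):(starts[i] + lens[i])] <- bases[i]
    hp <- data.frame(chrom = chrom, start = starts, end = starts + lens,
                     base = bases, stringsAsFactors = FALSE)
  }
  genome <- stats::setNames(paste(seq_chars, collapse = ""), chrom)
  list(genome = genome, models = models, homopolymers = hp)
}

# Partition of the toy chromosome into exonic / intronic / intergenic
# intervals (0-based half-open), used for site placement and truth labels.
.genome_regions <- function(genome, models) {
  chrom <- names(genome)[1]
  len <- nchar(genome[[1]])
  ex <- models$features[models$features$type == "exon", ]
  ex <- ex[order(ex$start), ]
  exonic <- .merge_intervals(ex$start, ex$end)
  g <- models$genes[order(models$genes$start), ]
  genic <- .merge_intervals(g$start, g$end)
  intronic <- .interval_diff(genic, exonic)
  intergenic <- .interval_diff(data.frame(start = 0L, end = len), genic)
  list(exonic = cbind(exonic, chrom = chrom),
       intronic = cbind(intronic, chrom = chrom),
       intergenic = cbind(intergenic, chrom = chrom))
}

.merge_intervals <- function(start, end) {
  if (!length(start)) return(data.frame(start = integer(), end = integer()))
  o <- order(start)
  start <- start[o]; end <- end[o]
  out_s <- start[1]; out_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= out_e[length(out_e)]) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], end[i])
    } else {
      out_s <- c(out_s, start[i]); out_e <- c(out_e, end[i])
    }
  }
  data.frame(start = out_s, end = out_e)
}

# set difference a \ b for merged, sorted interval frames
.interval_diff <- function(a, b) {
  res_s <- integer(); res_e <- integer()
  for (i in seq_len(nrow(a))) {
    cur <- a$start[i]
    overl <- b[b$end > a$start[i] & b$start < a$end[i], , drop = FALSE]
    if (nrow(overl)) overl <- overl[order(overl$start), , drop = FALSE]
    for (j in seq_len(nrow(overl))) {
      if (overl$start[j] > cur) {
        res_s <- c(res_s, cur); res_e <- c(res_e, overl$start[j])
      }
      cur <- max(cur, overl$end[j])
    }
    if (cur < a$end[i]) { res_s <- c(res_s, cur); res_e <- c(res_e, a$end[i]) }
  }
  data.frame(start = res_s, end = res_e)
}
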