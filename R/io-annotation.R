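#' Gene model container
#'
#' Holds gene bodies and sub-gene features (exons, CDS, 5'/3' UTR) in the
#' package-wide 0-based half-open coordinate convention. GTF input (1-based
#' inclusive) is converted on read; BED input is taken as-is.
#'
#' @param genes data.frame with `gene_id`, `biotype`
#'   (`protein_coding`/`lncRNA`/`other`), `chrom`, `start`, `end`, `strand`.
#' @param features data.frame with `gene_id`, `type` in
#'   `exon`/`CDS`/`UTR5`/`UTR3`, `chrom`, `start`, `end`.
#' @return object of class `gene_models`.
#' @export
gene_models <- function(genes, features) {
  stopifnot(all(c("gene_id", "biotype", "chrom", "start", "end") %in% names(genes)),
            all(c("gene_id", "type", "chrom", "start", "end") %in% names(features)))
  if (any(genes$start < 0) || any(genes$start >= genes$end))
    stop("gene intervals must satisfy 0 <= start < end")
  if (is.null(genes$strand)) genes$strand <- "+"
  # clamp features escaping their gene bounds (tolerated with a warning)
  gi <- match(features$gene_id, genes$gene_id)
  if (anyNA(gi)) stop("feature references unknown gene_id")
  esc <- features$start < genes$start[gi] | features$end > genes$end[gi]
  if (any(esc)) {
    warning(sum(esc), " feature(s) extend outside their gene bounds; clamped")
    features$start <- pmax(features$start, genes$start[gi])
    features$end <- pmin(features$end, genes$end[gi])
  }
  features <- features[order(features$gene_id, features$start), , drop = FALSE]
  rownames(genes) <- rownames(features) <- NULL
  structure(list(genes = genes, features = features), class = "gene_models")
}

#' @exportS3Method base::print
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes (%s)\n", nrow(x$genes),
              paste(names(table(x$genes$biotype)),
                    table(x$genes$biotype), sep = ":", collapse = ", ")))
  invisible(x)
}

#' Exon-exon junction boundaries
#'
#' One row per adjacent exon pair: the half-open end of the upstream exon
#' (`donor_end`) and the start of the downstream exon (`acceptor_start`),
#' both in internal coordinates. A k-exon gene yields k-1 junctions.
#'
#' @param models a `gene_models`.
#' @return data.frame `gene_id`, `chrom`, `donor_end`, `acceptor_start`.
#' @export
gene_junctions <- function(models) {
  ex <- models$features[models$features$type == "exon", , drop = FALSE]
  out <- lapply(split(ex, ex$gene_id), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2) return(NULL)
    data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1],
               donor_end = e$end[-nrow(e)], acceptor_start = e$start[-1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(), chrom = character(),
                      donor_end = integer(), acceptor_start = integer())
  rownames(out) <- NULL
  out
}

#' Read gene annotation (GTF or BED)
#'
#' GTF rows of type gene/exon/CDS/five_prime_utr/three_prime_utr are mapped
#' into the model; biotypes other than `protein_coding` and `lncRNA` are
#' kept as `"other"` (excluded from coding/non-coding tallies downstream).
#' A BED file yields one single-exon gene per line (biotype `"other"`).
#'
#' @param path annotation file path.
#' @param dialect `"gtf"` or `"bed"`.
#' @return a `gene_models`.
#' @export
read_annotation <- function(path, dialect = c("gtf", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    ids <- if (!is.null(gr$name) && !anyNA(gr$name)) gr$name
           else paste0("bed_", seq_along(gr))
    genes <- data.frame(gene_id = ids, biotype = "other",
                        chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr) - 1L,
                        end = GenomicRanges::end(gr),
                        strand = as.character(GenomicRanges::strand(gr)),
                        stringsAsFactors = FALSE)
    genes$strand[genes$strand == "*"] <- "."
    feats <- data.frame(gene_id = ids, type = "exon", chrom = genes$chrom,
                        start = genes$start, end = genes$end,
                        stringsAsFactors = FALSE)
    return(gene_models(genes, feats))
  }
  gr <- rtracklayer::import(path, format = "GTF")
  df <- data.frame(type = as.character(gr$type),
                   gene_id = gr$gene_id,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  bt_col <- intersect(c("gene_biotype", "gene_type", "biotype"),
                      names(S4Vectors::mcols(gr)))
  df$biotype <- if (length(bt_col)) as.character(S4Vectors::mcols(gr)[[bt_col[1]]])
                else NA_character_
  df$biotype[is.na(df$biotype)] <- "other"
  df$biotype[!df$biotype %in% c("protein_coding", "lncRNA")] <- "other"
  g <- df[df$type == "gene", , drop = FALSE]
  if (nrow(g) == 0) {  # infer gene bounds from features
    sp <- split(df, df$gene_id)
    g <- do.call(rbind, lapply(sp, function(d)
      data.frame(type = "gene", gene_id = d$gene_id[1], chrom = d$chrom[1],
                 start = min(d$start), end = max(d$end), strand = d$strand[1],
                 biotype = d$biotype[1], stringsAsFactors = FALSE)))
  }
  type_map <- c(exon = "exon", CDS = "CDS",
                five_prime_utr = "UTR5", three_prime_utr = "UTR3")
  f <- df[df$type %in% names(type_map), , drop = FALSE]
  f$type <- unname(type_map[f$type])
  genes <- data.frame(gene_id = g$gene_id, biotype = g$biotype,
                      chrom = g$chrom, start = g$start, end = g$end,
                      strand = g$strand, stringsAsFactors = FALSE)
  feats <- f[, c("gene_id", "type", "chrom", "start", "end")]
  gene_models(genes, feats)
}

#' Write gene models as GTF
#'
#' Inverse of [read_annotation()] for the GTF dialect (coordinates converted
#' back to 1-based inclusive).
#'
#' @param models a `gene_models`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  type_map <- c(exon = "exon", CDS = "CDS",
                UTR5 = "five_prime_utr", UTR3 = "three_prime_utr")
  g <- models$genes
  f <- models$features
  attr_of <- function(id, bt) sprintf('gene_id "%s"; gene_biotype "%s";', id, bt)
  bt <- g$biotype[match(f$gene_id, g$gene_id)]
  lines <- c(
    paste(g$chrom, "exprvar", "gene", g$start + 1L, g$end, ".",
          ifelse(g$strand %in% c("+", "-"), g$strand, "."), ".",
          attr_of(g$gene_id, g$biotype), sep = "\t"),
    paste(f$chrom, "exprvar", type_map[f$type], f$start + 1L, f$end, ".",
          ifelse(g$strand[match(f$gene_id, g$gene_id)] %in% c("+", "-"),
                 g$strand[match(f$gene_id, g$gene_id)], "."), ".",
          attr_of(f$gene_id, bt), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings returning plain named uppercase character
#' vectors, which is all the simulator and the context scanners need.
#'
#' @param path FASTA file path.
#' @return `read_fasta`: named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate sequence names in FASTA: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  out <- toupper(as.character(ss))
  names(out) <- nm
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
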