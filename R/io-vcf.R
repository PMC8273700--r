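#' Read a VCF file into a call set
#'
#' Parses a VCF 4.x file (plain or gzipped) into the internal
#' [snp_callset()] model. Genotype strings are reduced to alt-allele
#' dosage; `"./."` (and half calls such as `"0/."`) map to missing. Phased
#' (`|`) and unphased (`/`) separators are treated identically: the pipeline
#' never re-phases, phase only enters through the ASE module's haplotype
#' count tables. Per-genotype depth is taken from FORMAT/DP when present,
#' falling back to the sum of AD, else 0.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file.
#' @return a `snp_callset`; the number of half-called genotypes treated as
#'   missing is recorded in `attr(, "n_half_calls")`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n <- nrow(fix)
  samples <- colnames(v@gt)[-1]
  if (n == 0L) {
    sites <- data.frame(chrom = character(), pos = integer(),
                        id = character(), ref = character(),
                        alt = character(), qual = numeric(),
                        filter = character())
    return(snp_callset(sites,
                       gt = matrix(NA_integer_, 0, length(samples)),
                       dp = matrix(NA_integer_, 0, length(samples)),
                       samples = samples))
  }
  info_num <- function(key) {
    x <- suppressWarnings(vcfR::extract.info(v, element = key, as.numeric = TRUE))
    if (is.null(x)) rep(NA_real_, n) else as.numeric(x)
  }
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      id = fix$ID, ref = fix$REF, alt = fix$ALT,
                      qual = suppressWarnings(as.numeric(fix$QUAL)),
                      filter = fix$FILTER,
                      qd = info_num("QD"), fs = info_num("FS"),
                      sor = info_num("SOR"), mq = info_num("MQ"),
                      mq_rank_sum = info_num("MQRankSum"),
                      read_pos_rank_sum = info_num("ReadPosRankSum"),
                      stringsAsFactors = FALSE)

  gt_chr <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_chr)) stop("VCF has no GT FORMAT field")
  toks <- unique(as.vector(gt_chr))
  toks <- toks[!is.na(toks)]
  bad <- toks[!grepl("^[0-9.]+([/|][0-9.]+)*$", toks)]
  if (length(bad))
    stop("unknown GT token(s): ", paste(bad, collapse = ", "))
  # dosage = number of non-ref alleles; any missing allele => missing call
  dose_lookup <- vapply(toks, function(tk) {
    al <- strsplit(tk, "[/|]")[[1]]
    if (any(al == ".")) NA_integer_ else sum(al != "0")
  }, integer(1))
  half <- vapply(toks, function(tk) {
    al <- strsplit(tk, "[/|]")[[1]]
    any(al == ".") && !all(al == ".")
  }, logical(1))
  gt <- matrix(dose_lookup[match(as.vector(gt_chr), toks)],
               nrow = n, dimnames = list(NULL, samples))
  n_half <- sum(half[match(as.vector(gt_chr), toks)], na.rm = TRUE)

  ad_chr <- suppressWarnings(vcfR::extract.gt(v, element = "AD"))
  ad_ref <- ad_alt <- matrix(NA_integer_, n, length(samples))
  if (!is.null(ad_chr)) {
    parts <- strsplit(as.vector(ad_chr), ",", fixed = TRUE)
    ad_ref[] <- vapply(parts, function(p)
      if (length(p) < 1 || is.na(p[1]) || p[1] == ".") NA_integer_
      else as.integer(p[1]), integer(1))
    ad_alt[] <- vapply(parts, function(p) {
      if (length(p) < 2) return(NA_integer_)
      alts <- suppressWarnings(as.integer(p[-1]))
      if (all(is.na(alts))) NA_integer_ else sum(alts, na.rm = TRUE)
    }, integer(1))
  }
  dp_chr <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  dp <- matrix(if (is.null(dp_chr)) NA_real_ else as.vector(dp_chr),
               nrow = n, dimnames = list(NULL, samples))
  # precedence: FORMAT/DP, else sum(AD), else 0
  fallback <- ad_ref + ad_alt
  dp[is.na(dp)] <- fallback[is.na(dp)]
  dp[is.na(dp)] <- 0
  storage.mode(dp) <- "integer"

  out <- snp_callset(sites, gt, dp, ad_ref, ad_alt, samples)
  attr(out, "n_half_calls") <- n_half
  out
}

#' Write a call set to a VCF file
#'
#' Emits VCF 4.2 with `GT:AD:DP` FORMAT fields and the site statistics the
#' pipeline uses (QD, FS, and SOR/MQ/rank sums when present) as INFO keys.
#' Missing genotypes are written as `"./."`.
#'
#' @param cs a `snp_callset`, sorted by (chrom, pos).
#' @param path output path; a `.gz` suffix gzip-compresses.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cs, path) {
  s <- cs$sites
  if (!identical(order(s$chrom, s$pos), seq_along(s$pos)))
    stop("sites must be sorted by (chrom, pos) before writing")
  info_keys <- c(QD = "qd", FS = "fs", SOR = "sor", MQ = "mq",
                 MQRankSum = "mq_rank_sum", ReadPosRankSum = "read_pos_rank_sum")
  present <- names(info_keys)[vapply(info_keys, function(cl)
    any(!is.na(s[[cl]])), logical(1))]
  hdr <- c("##fileformat=VCFv4.2",
           "##source=exprvar",
           sprintf("##contig=<ID=%s>", unique(s$chrom)),
           sprintf(paste0("##INFO=<ID=%s,Number=1,Type=Float,",
                          "Description=\"Site statistic\">"), present),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", cs$samples), collapse = "\t"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(s) == 0L) return(invisible(path))

  num_fmt <- function(x) ifelse(is.na(x), NA, formatC(x, format = "g", digits = 6))
  info <- rep("", nrow(s))
  for (key in present) {
    val <- num_fmt(s[[info_keys[[key]]]])
    piece <- ifelse(is.na(val), "", paste0(key, "=", val))
    info <- ifelse(piece == "", info,
                   ifelse(info == "", piece, paste(info, piece, sep = ";")))
  }
  info[info == ""] <- "."
  gt_str <- matrix(c("0/0", "0/1", "1/1")[cs$gt + 1L], nrow = nrow(s))
  gt_str[is.na(gt_str)] <- "./."
  ad_str <- matrix(paste0(cs$ad_ref, ",", cs$ad_alt), nrow = nrow(s))
  ad_str[is.na(cs$ad_ref) | is.na(cs$ad_alt)] <- "."
  dp_str <- matrix(as.character(cs$dp), nrow = nrow(s))
  dp_str[is.na(dp_str)] <- "."
  cells <- matrix(paste(gt_str, ad_str, dp_str, sep = ":"), nrow = nrow(s))
  body <- paste(s$chrom, s$pos,
                ifelse(is.na(s$id) | s$id == "", ".", s$id),
                s$ref, s$alt,
                ifelse(is.na(s$qual), ".", formatC(s$qual, format = "g", digits = 8)),
                ifelse(is.na(s$filter) | s$filter == "", ".", s$filter),
                info, "GT:AD:DP",
                apply(cells, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(body, con)
  invisible(path)
}
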