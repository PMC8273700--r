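# In-code fixtures shared across the suite.

# A call set with explicit matrices; site metadata is auto-generated.
make_callset <- function(gt, dp = NULL, chrom = "chr1", pos = NULL,
                         ref = "A", alt = "G", qd = NA_real_, fs = NA_real_,
                         sor = NA_real_, mq = NA_real_) {
  gt <- as.matrix(gt)
  n <- nrow(gt)
  if (is.null(dp)) dp <- matrix(10L, n, ncol(gt))
  if (is.null(pos)) pos <- seq_len(n) * 100L
  sites <- data.frame(chrom = chrom, pos = pos, id = NA_character_,
                      ref = rep_len(ref, n), alt = rep_len(alt, n),
                      qual = 50, filter = ".",
                      qd = rep_len(qd, n), fs = rep_len(fs, n),
                      sor = rep_len(sor, n), mq = rep_len(mq, n),
                      stringsAsFactors = FALSE)
  snp_callset(sites, gt, as.matrix(dp),
              samples = paste0("s", seq_len(ncol(gt))))
}

# A random biallelic call set (for round-trip and property tests).
random_callset <- function(n_sites = 20, n_samples = 4, seed = 1) {
  set.seed(seed)
  gt <- matrix(sample(c(0:2, NA), n_sites * n_samples, replace = TRUE),
               n_sites, n_samples)
  dp <- matrix(rpois(n_sites * n_samples, 15), n_sites, n_samples)
  cs <- make_callset(gt, dp,
                     pos = sort(sample.int(1e5, n_sites)),
                     ref = sample(c("A", "C", "G", "T"), n_sites, TRUE),
                     qd = round(runif(n_sites, 0, 30), 3),
                     fs = round(runif(n_sites, 0, 80), 3))
  # alt must differ from ref
  cs$sites$alt <- c(A = "G", C = "T", G = "A", T = "C")[cs$sites$ref]
  cs$ad_alt[] <- pmin(cs$dp, matrix(rpois(n_sites * n_samples, 5),
                                    n_sites, n_samples))
  cs$ad_ref[] <- cs$dp - cs$ad_alt
  cs
}

# Minimal truth object so emit_callset() can run on hand-built counts.
make_min_truth <- function(n_sites, samples, gt_true = NULL) {
  sites <- data.frame(chrom = "chr1", pos = seq_len(n_sites) * 10L,
                      pos0 = seq_len(n_sites) * 10L - 1L,
                      ref = "A", alt = "G", af = 0.3,
                      feature_class = "exonic", gene_id = NA_character_,
                      stringsAsFactors = FALSE)
  if (is.null(gt_true))
    gt_true <- matrix(1L, n_sites, length(samples))
  structure(list(sites = sites, gt = gt_true, samples = samples),
            class = "sim_truth")
}

# Independent two-sided conditional-exact p for a 2x2 table: explicit
# enumeration of all tables with the observed margins using lchoose, never
# dhyper (the implementation's path).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  x <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  pmf <- exp(logp)
  obs <- pmf[x == a]
  min(1, sum(pmf[pmf <= obs * (1 + 1e-7)]))
}

# Brute-force SNP cluster flags: slide every possible window start.
oracle_cluster_flags <- function(pos, window = 35, min_snps = 3) {
  flag <- rep(FALSE, length(pos))
  if (length(pos) == 0) return(flag)
  for (start in (min(pos) - window + 1):max(pos)) {
    inside <- pos >= start & pos < start + window
    if (sum(inside) >= min_snps) flag <- flag | inside
  }
  flag
}

# Step-up BH oracle following the definition directly.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}
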