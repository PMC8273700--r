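test_that("eligibility tiers nest and count genes per biotype", {
  set.seed(59)
  n_genes <- 50
  gene_expr <- data.frame(
    gene_id = sprintf("g%02d", 1:n_genes),
    biotype = sample(c("protein_coding", "lncRNA"), n_genes, TRUE, c(0.7, 0.3)),
    tpm = rlnorm(n_genes, 1, 1.5))
  site_table <- data.frame(
    gene_id = sample(c(gene_expr$gene_id, NA), 400, TRUE),
    region = sample(c("exon", "intron"), 400, TRUE),
    gt_selected = runif(400) < 0.8)
  site_table$maf_ok <- site_table$gt_selected & runif(400) < 0.7
  site_table$het_ok <- site_table$maf_ok & runif(400) < 0.6
  for (region in c("exons", "exons_introns")) {
    tiers <- ase_eligible_genes(gene_expr, site_table, tpm_min = 1,
                                region = region)
    # brute-force recount
    st <- site_table[!is.na(site_table$gene_id), ]
    if (region == "exons") st <- st[st$region == "exon", ]
    for (i in seq_len(nrow(tiers))) {
      qual <- switch(tiers$tier[i],
                     tier1 = st$gt_selected,
                     tier2 = st$gt_selected & st$maf_ok,
                     tier3 = st$gt_selected & st$maf_ok & st$het_ok)
      genes_bt <- gene_expr$gene_id[gene_expr$tpm >= 1 &
                                      gene_expr$biotype == tiers$biotype[i]]
      per_gene <- table(st$gene_id[qual])
      hit <- intersect(names(per_gene), genes_bt)
      expect_equal(tiers$n_genes[i], length(hit))
      if (length(hit))
        expect_equal(tiers$s_per_g[i], mean(as.numeric(per_gene[hit])))
    }
    # tiers are nested
    for (bt in unique(tiers$biotype)) {
      v <- tiers$n_genes[tiers$biotype == bt]
      expect_true(all(diff(v) <= 0))
    }
  }
  # a gene whose only SNP fails MAF stays in tier 1 only
  ge <- data.frame(gene_id = "g", biotype = "protein_coding", tpm = 5)
  st1 <- data.frame(gene_id = "g", region = "exon", gt_selected = TRUE,
                    maf_ok = FALSE, het_ok = FALSE)
  t1 <- ase_eligible_genes(ge, st1)
  expect_equal(t1$n_genes[t1$tier == "tier1" & t1$biotype == "protein_coding"], 1)
  expect_equal(t1$n_genes[t1$tier == "tier2" & t1$biotype == "protein_coding"], 0)
})

test_that("haplotype aggregation picks the densest block and sums per phase", {
  one <- data.frame(gene_id = "g", sample = "s", block = 1, pos = 10,
                    hapA = 12, hapB = 8)
  agg <- aggregate_haplotype_counts(one)
  expect_equal(agg$count_hapA, 12)
  expect_equal(agg$count_hapB, 8)
  two <- data.frame(gene_id = "g", sample = "s", block = 1, pos = c(10, 20),
                    hapA = c(10, 8), hapB = c(5, 7))
  agg2 <- aggregate_haplotype_counts(two)
  expect_equal(agg2$count_hapA, 18)
  expect_equal(agg2$count_hapB, 12)
  expect_equal(agg2$n_snps_in_haplotype, 2)
  # block with more SNPs wins over a deeper 2-SNP block
  mixed <- data.frame(gene_id = "g", sample = "s",
                      block = c(1, 1, 1, 2, 2), pos = c(1, 2, 3, 4, 5),
                      hapA = c(2, 2, 2, 50, 50), hapB = c(1, 1, 1, 40, 40))
  agg3 <- aggregate_haplotype_counts(mixed)
  expect_equal(agg3$count_hapA, 6)
  # tie on SNPs: more reads wins; tie on reads: leftmost block wins
  tie <- data.frame(gene_id = "g", sample = "s",
                    block = c(1, 1, 2, 2), pos = c(1, 2, 3, 4),
                    hapA = c(2, 2, 30, 30), hapB = c(1, 1, 20, 20))
  expect_equal(aggregate_haplotype_counts(tie)$count_hapA, 60)
  tie2 <- data.frame(gene_id = "g", sample = "s",
                     block = c(2, 2, 1, 1), pos = c(3, 4, 1, 2),
                     hapA = c(5, 5, 5, 5), hapB = c(2, 2, 2, 2))
  expect_equal(aggregate_haplotype_counts(tie2)$n_snps_in_haplotype, 2)
})

test_that("the exact binomial ASE test matches closed forms and symmetry", {
  expect_equal(binomial_ase_test(10, 10), 1)
  expect_equal(binomial_ase_test(10, 0), 2 * 0.5^10)
  expect_true(is.na(binomial_ase_test(0, 0)))
  set.seed(61)
  for (i in 1:20) {
    a <- rpois(1, 20); b <- rpois(1, 20)
    expect_equal(binomial_ase_test(a, b), binomial_ase_test(b, a))
  }
  # p decreases as imbalance grows at fixed total
  p_seq <- binomial_ase_test(c(15, 18, 21, 24, 27), c(15, 12, 9, 6, 3))
  expect_true(all(diff(p_seq) < 0))
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(0.01)$q, 0.01)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03))$q, oracle_bh(c(0.01, 0.04, 0.03)))
  expect_false(any(bh_adjust(rep(1, 10))$reject))
  set.seed(67)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    bh <- bh_adjust(p)
    expect_equal(bh$q, oracle_bh(p))
    expect_true(all(bh$q >= p))
  }
})

test_that("ASE gene calls require >= 10 reads and >= 2 significant samples", {
  counts <- data.frame(
    gene_id = c("g1", "g1", "g1", "g2", "g2", "g3"),
    sample = c("s1", "s2", "s3", "s1", "s2", "s1"),
    count_hapA = c(40, 38, 20, 9, 0, 30),
    count_hapB = c(0, 1, 18, 0, 0, 28))
  res <- call_ase_genes(counts, min_samples = 2)
  # g2: 9 + 0 reads in s1, 0 + 0 in s2 -> never eligible
  expect_false("g2" %in% res$genes$gene_id)
  expect_true(res$genes$is_ase[res$genes$gene_id == "g1"])   # 2 extreme samples
  expect_false(res$genes$is_ase[res$genes$gene_id == "g3"])  # balanced
  # eligibility switch: >= 10 total reads makes (9, 1) testable
  counts2 <- data.frame(gene_id = "g", sample = "s",
                        count_hapA = 9, count_hapB = 1)
  expect_equal(nrow(call_ase_genes(counts2)$per_sample), 0)
  expect_equal(nrow(call_ase_genes(counts2,
                                   min_reads_mode = "total")$per_sample), 1)
  # one significant sample is not enough
  one_sig <- data.frame(gene_id = "g", sample = "s1",
                        count_hapA = 40, count_hapB = 0)
  expect_false(call_ase_genes(one_sig)$genes$is_ase)
})

test_that("population ASE summaries report fractions and sharing", {
  g1 <- data.frame(gene_id = c("a", "b", "c"), n_tested_samples = 3,
                   n_significant_samples = c(3, 0, 2),
                   median_abs_log2_afc = 1, is_ase = c(TRUE, FALSE, TRUE))
  same <- population_ase_summary(list(p1 = g1, p2 = g1))
  expect_equal(unname(same$shared["n_shared_all"]), 2)
  expect_equal(same$per_population$fraction_ase, c(2 / 3, 2 / 3))
  g2 <- g1; g2$is_ase <- c(FALSE, TRUE, FALSE)
  disjoint <- population_ase_summary(list(p1 = g1, p2 = g2))
  expect_equal(unname(disjoint$shared["n_shared_all"]), 0)
})
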