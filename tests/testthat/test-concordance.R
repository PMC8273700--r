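make_keyed_callset <- function(pos, gt, dp = NULL) {
  make_callset(gt, dp, pos = pos)
}

test_that("detection precision/recall is plain set arithmetic on site keys", {
  t3 <- make_keyed_callset(c(100, 200, 300), matrix(0, 3, 2))
  r3 <- make_keyed_callset(c(200, 300, 400), matrix(0, 3, 2))
  pr <- detection_precision_recall(t3, r3)
  expect_equal(pr$precision, 2 / 3)
  expect_equal(pr$recall, 2 / 3)
  same <- detection_precision_recall(t3, t3)
  expect_equal(c(same$precision, same$recall), c(1, 1))
  # swapping test and reference swaps precision and recall
  sw <- detection_precision_recall(r3, t3)
  expect_equal(sw$precision, pr$recall)
  expect_equal(sw$recall, pr$precision)
  # empty test set is flagged undefined
  empty <- subset_sites(t3, rep(FALSE, 3))
  expect_true(detection_precision_recall(empty, r3)$undefined)
  # a mask restricts the compared region
  mask <- data.frame(chrom = "chr1", start = 0, end = 250)
  pr_m <- detection_precision_recall(t3, r3, mask)
  expect_equal(pr_m$n_test, 2)   # sites 100, 200
  expect_equal(pr_m$precision, 1 / 2)
})

test_that("site identity requires the matching alt allele", {
  t1 <- make_keyed_callset(100, matrix(0, 1, 2))
  r1 <- make_keyed_callset(100, matrix(0, 1, 2))
  r1$sites$alt <- "T"
  expect_equal(detection_precision_recall(t1, r1)$n_shared, 0)
})

test_that("genotype concordance counts equal calls among comparable pairs", {
  gt <- matrix(c(0, 1, 2, 1, 0, 2, 1, 1, 0, 2), 5, 2)
  cs <- make_callset(gt, matrix(20, 5, 2))
  expect_equal(genotype_concordance(cs, cs)$concordance, 100)
  ref <- cs
  ref$gt[1, 1] <- 2                       # one mismatch in 10 pairs
  expect_equal(genotype_concordance(cs, ref)$concordance, 90)
  # pairs below dp_min or uncalled are excluded
  cs2 <- cs; cs2$dp[1, 1] <- 3
  expect_equal(genotype_concordance(cs2, ref, dp_min = 5)$concordance, 100)
  ref2 <- ref; ref2$gt[1, 1] <- NA
  expect_equal(genotype_concordance(cs, ref2)$concordance, 100)
})

test_that("concordance grid matches a brute-force recomputation", {
  set.seed(17)
  test <- random_callset(50, 6, seed = 23)
  ref <- random_callset(50, 6, seed = 23)
  flip <- sample(length(ref$gt), 40)
  ref$gt[flip] <- (ref$gt[flip] + 1) %% 3
  grid <- concordance_grid(test, ref, cr_values = c(0, 0.5),
                           dp_cr_values = c(0, 0.2, 0.5), k = 5)
  expect_equal(grid$retained_pct[grid$cr_min == 0 & grid$dp_cr_min == 0], 100)
  for (i in seq_len(nrow(grid))) {
    keep <- call_rate(test$gt) >= grid$cr_min[i] &
      dp_filtered_call_rate(test, 5) >= grid$dp_cr_min[i]
    expect_equal(grid$n_sites[i], sum(keep))
    tg <- test$gt[keep, , drop = FALSE]
    rg <- ref$gt[keep, , drop = FALSE]
    td <- test$dp[keep, , drop = FALSE]
    cmp <- !is.na(tg) & !is.na(rg) & td >= 5
    if (any(cmp))
      expect_equal(grid$concordance[i], 100 * mean(tg[cmp] == rg[cmp]))
  }
  # retention is monotone along each axis
  r00 <- grid$retained_pct[grid$cr_min == 0 & grid$dp_cr_min == 0.2]
  r50 <- grid$retained_pct[grid$cr_min == 0.5 & grid$dp_cr_min == 0.2]
  expect_lte(r50, r00)
})

test_that("tissue merging prefers the deepest call on discordance", {
  liver <- make_keyed_callset(c(100, 200), rbind(c(1, NA), c(0, 0)),
                              rbind(c(30, 0), c(8, 8)))
  blood <- make_keyed_callset(c(100, 200), rbind(c(0, 1), c(0, 0)),
                              rbind(c(6, 12), c(8, 8)))
  m <- merge_tissues(list(liver = liver, blood = blood))
  expect_equal(unname(m$gt[m$sites$pos == 100, ]), c(1, 1))  # 30X beats 6X; blood-only call kept
  expect_equal(unname(m$dp[m$sites$pos == 100, ]), c(30, 12))
  # equal-depth discordance keeps the first tissue and counts the tie
  blood2 <- blood; blood2$dp[1, 1] <- 30
  m2 <- merge_tissues(list(liver = liver, blood = blood2))
  expect_equal(unname(m2$gt[m2$sites$pos == 100, 1]), 1)
  expect_equal(attr(m2, "n_dp_ties"), 1)
  expect_equal(attr(m, "n_dp_ties"), 0)
})

test_that("tissue merging is idempotent and unions sites", {
  a <- make_keyed_callset(c(100, 200), rbind(c(1, 0), c(0, 2)))
  b <- make_keyed_callset(c(200, 300), rbind(c(0, 2), c(1, 1)))
  m <- merge_tissues(list(a = a, b = b))
  expect_equal(nrow(m$sites), 3)
  m2 <- merge_tissues(list(m, m))
  expect_equal(m2$gt, m$gt)
  expect_equal(m2$dp, m$dp)
  expect_equal(site_keys(m2), site_keys(m))
  rep_df <- attr(merge_tissues(list(a = a, b = b)), "concordance_report")
  expect_equal(unique(rep_df$dp_min), c(0, 5, 10))
})

test_that("RNA-vs-DNA concordance improves with the depth threshold", {
  cfg <- sim_config(seed = 91, n_genes = 20)
  sim <- emit_callsets(cfg, withr::local_tempdir())
  rna <- sim$callsets$rna_liver; dna <- sim$callsets$dna
  c0 <- genotype_concordance(rna, dna, dp_min = 0)$concordance
  c5 <- genotype_concordance(rna, dna, dp_min = 5)$concordance
  expect_gte(c5, c0)
})
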