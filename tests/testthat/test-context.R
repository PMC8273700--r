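test_that("SNP cluster flags follow the 3-in-35bp rule", {
  expect_equal(flag_snp_clusters(c(100, 110, 130)), rep(TRUE, 3))
  expect_equal(flag_snp_clusters(c(100, 110)), rep(FALSE, 2))
  expect_equal(flag_snp_clusters(c(100, 200, 300)), rep(FALSE, 3))
  # a 4th SNP coverable by a qualifying window is flagged too
  expect_equal(flag_snp_clusters(c(100, 101, 102, 130)), rep(TRUE, 4))
  expect_equal(flag_snp_clusters(c(100, 101, 102, 140)),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_error(flag_snp_clusters(c(10, 5)), "sorted")
})

test_that("cluster flags equal the brute-force window scan", {
  set.seed(29)
  for (i in 1:200) {
    pos <- sort(sample.int(500, sample(3:25, 1)))
    pos <- pos[!duplicated(pos)]
    expect_equal(flag_snp_clusters(pos), oracle_cluster_flags(pos),
                 info = paste(pos, collapse = ","))
  }
})

test_that("homopolymer runs are maximal runs of length >= 5", {
  runs <- find_homopolymers("GGAAAAAG")
  expect_equal(runs$start, 2)
  expect_equal(runs$end, 7)
  expect_equal(runs$base, "A")
  expect_equal(nrow(find_homopolymers("GGAAAAG")), 0)   # A x 4
  # SNP on the first base of a run is flagged; adjacent outside is not
  expect_true(flag_homopolymer(2, runs))
  expect_true(flag_homopolymer(6, runs))
  expect_false(flag_homopolymer(1, runs))
  expect_false(flag_homopolymer(7, runs))
  expect_true(flag_homopolymer(1, runs, pad = 1))
  # no run of length >= 5 exists outside the reported intervals
  set.seed(31)
  seqs <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  runs2 <- find_homopolymers(seqs)
  chars <- strsplit(seqs, "")[[1]]
  for (i in seq_len(nchar(seqs) - 4)) {
    is_run <- length(unique(chars[i:(i + 4)])) == 1
    covered <- any(runs2$start <= i - 1 & runs2$end >= i + 4)
    expect_equal(is_run, covered)
  }
})

test_that("junction proximity uses exonic flanks only", {
  j <- data.frame(gene_id = "g", chrom = "chr1",
                  donor_end = 200, acceptor_start = 300)
  expect_true(flag_junction_proximity(195, j))    # within last 5 exon bases
  expect_false(flag_junction_proximity(194, j))   # distance 6
  expect_true(flag_junction_proximity(199, j))
  expect_false(flag_junction_proximity(200, j))   # first intron base
  expect_false(flag_junction_proximity(299, j))   # last intron base
  expect_true(flag_junction_proximity(300, j))    # first downstream exon base
  expect_true(flag_junction_proximity(304, j))
  expect_false(flag_junction_proximity(305, j))
  # single-exon gene has no junctions, so nothing is flagged
  empty_j <- j[0, ]
  expect_false(flag_junction_proximity(200, empty_j))
})

test_that("feature classification respects the precedence order", {
  genes <- data.frame(gene_id = c("g1", "g2"),
                      biotype = c("protein_coding", "lncRNA"),
                      chrom = "chr1", start = c(100, 150), end = c(500, 700),
                      strand = "+")
  feats <- rbind(
    data.frame(gene_id = "g1", type = "exon", chrom = "chr1",
               start = c(100, 300), end = c(200, 400)),
    data.frame(gene_id = "g1", type = "CDS", chrom = "chr1",
               start = 130, end = 200),
    data.frame(gene_id = "g1", type = "UTR5", chrom = "chr1",
               start = 100, end = 130),
    data.frame(gene_id = "g2", type = "exon", chrom = "chr1",
               start = 600, end = 700))
  m <- gene_models(genes, feats)
  pos <- c(150, 110, 320, 250, 650, 50)
  cls <- classify_feature(rep("chr1", 6), pos, m)
  # 150 is CDS of g1 even though it is intron of g2 (precedence)
  expect_equal(cls, c("CDS", "UTR5", "exon_noncoding", "intron",
                      "exon_noncoding", "intergenic"))
  # classification partitions every SNP
  expect_equal(sum(table(cls)), 6)
})

test_that("context annotation fills all four flag columns", {
  cfg <- sim_config(seed = 37, n_genes = 10, homopolymer_rate = 1)
  sim <- emit_callsets(cfg, withr::local_tempdir())
  ann <- annotate_context(sim$callsets$dna, sim$genome$models,
                          sim$genome$genome)
  s <- ann$sites
  expect_true(all(c("in_cluster", "in_homopolymer", "near_junction",
                    "feature_class") %in% names(s)))
  # feature classes agree with the simulator's ground truth
  rows <- attr(sim$callsets$dna, "truth_rows")
  truth_class <- sim$truth$sites$feature_class[rows]
  mapped <- c(CDS = "exonic", UTR5 = "exonic", UTR3 = "exonic",
              exon_noncoding = "exonic", intron = "intronic",
              intergenic = "intergenic")[s$feature_class]
  expect_equal(unname(mapped), truth_class)
})

test_that("flag enrichment reproduces the ratio and chi-square arithmetic", {
  eq <- flag_enrichment(50, 1000, 50, 1000)
  expect_equal(eq$ratio, 1)
  expect_gt(eq$p_value, 0.99)
  enr <- flag_enrichment(509, 10000, 355, 10000)
  expect_equal(round(enr$ratio, 2), 1.43)
  # Pearson statistic recomputed from the closed form
  tab <- matrix(c(509, 10000 - 509, 355, 10000 - 355), 2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - expected)^2 / expected)
  expect_equal(enr$p_value, pchisq(x2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(flag_enrichment(0, 0, 1, 10), "empty")
})
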