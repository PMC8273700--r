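test_that("toy genome has the requested structure and junction count", {
  cfg <- sim_config(seed = 11, n_genes = 1, exons_per_gene = c(3, 3))
  g <- build_toy_genome(cfg)
  expect_equal(nrow(g$models$genes), 1)
  expect_equal(sum(g$models$features$type == "exon"), 3)
  expect_equal(nrow(gene_junctions(g$models)), 2)  # exons - 1
  # injected homopolymer truth intervals are real runs in the sequence
  cfg2 <- sim_config(seed = 12, n_genes = 10, homopolymer_rate = 1)
  g2 <- build_toy_genome(cfg2)
  runs <- find_homopolymers(g2$genome[[1]], 5)
  expect_gt(nrow(g2$homopolymers), 0)
  for (i in seq_len(nrow(g2$homopolymers))) {
    covered <- any(runs$start <= g2$homopolymers$start[i] &
                     runs$end >= g2$homopolymers$end[i])
    expect_true(covered)
  }
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 99, n_genes = 8)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  emit_callsets(cfg, d1)
  emit_callsets(cfg, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_equal(f1, f2)
  for (f in f1)
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
})

test_that("population truth follows Hardy-Weinberg proportions", {
  # allele frequency pinned near 0.3 by a concentrated Beta spectrum
  cfg <- sim_config(seed = 21, n_genes = 40, n_individuals = 20,
                    maf_beta = c(30000, 70000),
                    site_density_kb = c(exonic = 35, intronic = 35,
                                        intergenic = 35))
  g <- build_toy_genome(cfg)
  tr <- simulate_population_truth(cfg, g)
  n_geno <- length(tr$gt)
  expect_gt(nrow(tr$sites), 5000)
  freqs <- c(mean(tr$gt == 0), mean(tr$gt == 1), mean(tr$gt == 2))
  expected <- c(0.49, 0.42, 0.09)
  se <- sqrt(expected * (1 - expected) / n_geno)
  expect_true(all(abs(freqs - expected) <= 3 * se))
  # degenerate frequency: p = 0 gives all hom-ref haplotypes
  cfg0 <- sim_config(seed = 22, n_genes = 5, maf_beta = c(1e-6, 1e6))
  tr0 <- simulate_population_truth(cfg0, build_toy_genome(cfg0))
  expect_true(all(tr0$gt == 0))
})

test_that("DNA coverage model gives the expected pooled population depth", {
  cfg <- sim_config(seed = 31, n_individuals = 6, dna_depth = 20, n_genes = 10)
  g <- build_toy_genome(cfg)
  tr <- simulate_population_truth(cfg, g)
  cnt <- simulate_coverage_and_counts(cfg, tr)
  pooled <- rowSums(cnt$dna$dp)
  # 6 individuals x 20X = 120 reads at the population level on average
  expect_equal(mean(pooled), 120,
               tolerance = 3 * sqrt(120 / length(pooled)) / 120)
})

test_that("RNA depth tracks expression and honours the noise floor", {
  cfg <- sim_config(seed = 41, n_genes = 25, noise_floor = 0,
                    error_rate = 0)
  g <- build_toy_genome(cfg)
  tr <- simulate_population_truth(cfg, g)
  cnt <- simulate_coverage_and_counts(cfg, tr)
  rna <- cnt$rna$liver
  inter <- tr$sites$feature_class == "intergenic"
  expect_true(all(rna$dp[inter, ] == 0))       # no transcription, no reads
  # mean exonic depth regresses on TPM with slope ~ rna_libsize_factor
  ex <- which(tr$sites$feature_class == "exonic" & !is.na(tr$sites$gene_id))
  tpm <- tr$tpm[match(tr$sites$gene_id[ex], rownames(tr$tpm)), 1]
  mdp <- rowMeans(rna$dp[ex, ])
  slope <- coef(lm(mdp ~ tpm))[["tpm"]]
  expect_equal(slope, cfg$rna_libsize_factor, tolerance = 0.05)
  # error-free hom-alt sites carry no reference reads
  hom_alt <- tr$gt == 2
  expect_true(all((cnt$dna$dp - cnt$dna$alt)[hom_alt] == 0))
})

test_that("the simulated caller applies its minimum-depth and ML rules", {
  samples <- c("s1", "s2")
  truth <- make_min_truth(2, samples)
  cfg <- sim_config(seed = 1, gt_call_min_dp = 3)
  assay <- list(dp = matrix(c(2, 100, 10, 100), 2, 2),
                alt = matrix(c(1, 50, 10, 1), 2, 2),
                strand = data.frame(ref_fwd = c(5, 5), ref_rev = c(5, 5),
                                    alt_fwd = c(5, 5), alt_rev = c(5, 5)))
  cs <- emit_callset(cfg, assay, truth)
  expect_equal(nrow(cs$sites), 2)
  expect_true(is.na(cs$gt[1, 1]))            # DP 2 < 3 -> "./."
  expect_equal(unname(cs$gt[1, 2]), 2)       # 10/10 alt reads -> hom-alt
  expect_equal(unname(cs$gt[2, 1]), 1)       # 50/100 -> het
  expect_equal(unname(cs$gt[2, 2]), 0)       # 1/100 -> hom-ref
})

test_that("error-free high-depth calls recover the true genotypes", {
  cfg <- sim_config(seed = 51, n_genes = 10, dna_depth = 1000, error_rate = 0)
  g <- build_toy_genome(cfg)
  tr <- simulate_population_truth(cfg, g)
  cnt <- simulate_coverage_and_counts(cfg, tr)
  cs <- emit_callset(cfg, cnt$dna, tr)
  rows <- attr(cs, "truth_rows")
  expect_true(all(cs$gt == tr$gt[rows, ], na.rm = TRUE))
  expect_equal(sum(is.na(cs$gt)), 0)
})

test_that("gene haplotype counts express the configured allelic ratios", {
  # aFC mapping: pi = 2^aFC / (1 + 2^aFC)
  expect_equal(2^0 / (1 + 2^0), 0.5)
  expect_equal(2^1 / (1 + 2^1), 2 / 3)
  cfg <- sim_config(seed = 61, n_genes = 300, n_individuals = 8,
                    tpm_meanlog = log(200), tpm_sdlog = 0,
                    ase_fraction = 1, afc_range = c(2, 2))
  g <- build_toy_genome(cfg)
  tr <- simulate_population_truth(cfg, g)
  hap <- simulate_gene_haplotype_counts(cfg, tr)
  act <- hap[hap$cis_active, ]
  # the major haplotype share converges on 2^2/(1+2^2) = 0.8
  share <- pmax(act$count_hapA, act$count_hapB) /
    (act$count_hapA + act$count_hapB)
  tot <- sum(act$count_hapA + act$count_hapB)
  expect_equal(mean(share), 0.8, tolerance = 3 * sqrt(0.8 * 0.2 / tot) + 0.002)
  bal <- hap[!hap$cis_active & hap$count_hapA + hap$count_hapB > 0, ]
  expect_equal(mean(bal$count_hapA / (bal$count_hapA + bal$count_hapB)), 0.5,
               tolerance = 0.01)
})
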