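test_that("cross-population union/intersection is set algebra on keys", {
  one <- cross_population_sets(list(a = c("k1", "k2")))
  expect_equal(one$union, 2)
  expect_equal(one$intersection, 2)
  dis <- cross_population_sets(list(a = "k1", b = "k2"))
  expect_equal(dis$intersection, 0)
  set.seed(71)
  pops <- lapply(1:3, function(i) sample(sprintf("s%03d", 1:200), 120))
  res <- cross_population_sets(setNames(pops, paste0("p", 1:3)))
  expect_equal(res$union, length(unique(unlist(pops))))
  expect_equal(res$intersection,
               sum(table(unlist(lapply(pops, unique))) == 3))
})

test_that("population summary table reproduces the published arithmetic", {
  tsv <- system.file("extdata", "population_snp_counts.tsv",
                     package = "exprvar")
  counts <- read.delim(tsv)
  tab <- population_summary_table(counts[, c("population", "single_total",
                                             "multi_total", "single_gt",
                                             "multi_gt", "single_maf",
                                             "multi_maf")])
  rjfh <- tab[tab$population == "RJFh", ]
  expect_equal(rjfh$ratio_total, 2.48)     # 2,604,288 / 1,050,035
  expect_equal(rjfh$ratio_gt, 2.18)
  expect_equal(rjfh$gt_over_total_single, 0.25)
  mean_row <- tab[tab$population == "Mean", ]
  expect_equal(mean_row$single_total, 1652954)
  expect_equal(mean_row$single_gt, 549634)
  expect_equal(mean_row$single_maf, 339539)
  expect_equal(mean_row$ratio_total, 1.54)
  # single population: the mean equals its own values
  solo <- population_summary_table(counts[1, c("population", "single_total",
                                               "multi_total", "single_gt",
                                               "multi_gt", "single_maf",
                                               "multi_maf")])
  expect_equal(solo$single_total[2], solo$single_total[1])
})

test_that("consequence accounting sums the severe categories", {
  res <- consequence_summary(c(stop_gained = 590, splice_site = 8126,
                               deleterious_missense = 16307,
                               start_or_stop_lost = 321))
  expect_equal(res$severe_total, 25344)
  empty <- consequence_summary(character())
  expect_equal(empty$grand_total, 0)
  expect_true(all(empty$counts == 0))
  expect_warning(res2 <- consequence_summary(c("stop_gained", "frameshift")),
                 "unknown")
  expect_equal(unname(res2$counts["other"]), 1)
})

test_that("ALT/ALT profiling uses the max rule over carrying populations", {
  homalt <- rbind(c(0, 0), c(0, 0.04), c(0, 0.2), c(0.5, 0))
  af <- rbind(c(0.1, 0.2), c(0.1, 0.2), c(0.1, 0.2), c(0, 0))
  prof <- altalt_profile(homalt, af)
  expect_equal(prof$class[1:3], c("altalt_absent", "altalt_le", "other"))
  expect_true(is.na(prof$class[4]))
  expect_equal(prof$n_excluded, 1)
  # a high hom-alt frequency in a non-carrying population is ignored
  homalt2 <- rbind(c(0, 0.9))
  af2 <- rbind(c(0.1, 0))
  expect_equal(altalt_profile(homalt2, af2)$class, "altalt_absent")
  # percentage rendering used in reports
  expect_equal(report_pct(5654, 25344), 22)
  expect_equal(report_pct(4072, 14496), 28)
})

test_that("IBS distance has metric-style structure", {
  gt <- cbind(a = c(0, 1, 2, 0), b = c(0, 1, 2, 0), c = c(2, 1, 0, 2))
  d <- ibs_distance(gt)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d["a", "b"], 0)             # identical individuals
  expect_equal(d, t(d))
  all0 <- cbind(x = rep(0, 5), y = rep(2, 5))
  expect_equal(ibs_distance(all0)["x", "y"], 1)   # maximal dissimilarity
  expect_true(all(d >= 0 & d <= 1))
  # missing genotypes are handled pairwise; a fully disjoint pair errors
  gtna <- cbind(x = c(0, NA), y = c(NA, 0))
  expect_error(ibs_distance(gtna), "no shared")
})

test_that("IBS clustering separates two diverged populations", {
  set.seed(73)
  n_sites <- 2000
  p1 <- rbeta(n_sites, 0.5, 0.5); p2 <- rbeta(n_sites, 0.5, 0.5)
  gt <- cbind(
    matrix(rbinom(n_sites * 6, 2, p1), n_sites, 6,
           dimnames = list(NULL, paste0("A", 1:6))),
    matrix(rbinom(n_sites * 6, 2, p2), n_sites, 6,
           dimnames = list(NULL, paste0("B", 1:6))))
  cl <- ibs_cluster(gt)
  expect_true(ape::is.monophyletic(cl$phylo, paste0("A", 1:6)))
  expect_true(ape::is.monophyletic(cl$phylo, paste0("B", 1:6)))
  expect_match(cl$newick, "^\\(.*\\);$")
})
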