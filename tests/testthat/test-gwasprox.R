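test_that("GWAS dataset metadata filter applies all three rules", {
  md <- data.frame(
    dataset = c("a", "b", "c", "d"),
    confidence = c("high", "high", "low", "high"),
    h2 = c(0.02, 0.005, 0.5, 0.02),
    h2_z = c(8, 10, 20, 6.9), stringsAsFactors = FALSE)
  kept <- filter_gwas_datasets(md)
  expect_equal(kept$dataset, "a")
  expect_equal(nrow(filter_gwas_datasets(md[0, ])), 0)
  expect_error(filter_gwas_datasets(md[, c("dataset", "h2")]), "lacks")
  # SNP p-value filter retains suggestive SNPs by default, invertible
  cat <- data.frame(pvalue = c(1e-8, 1e-3))
  expect_equal(nrow(filter_snps(cat)), 1)
  expect_equal(nrow(filter_snps(cat, keep = "above")), 1)
})

test_that("success ratios use the strict same-chromosome distance rule", {
  cpgs <- data.frame(cpg_id = "cg1", chromosome = "1", position = 100000)
  catalog <- data.frame(
    snp_id = sprintf("rs%d", 1:5),
    chromosome = c("1", "1", "1", "1", "2"),
    position = c(99500, 101200, 110000, 150000, 100000),
    pvalue = 1e-8, group = "A", stringsAsFactors = FALSE)
  sr1 <- success_ratios(cpgs, catalog, distances = 1000)
  expect_equal(sr1$success_ratio, 1 / 5)  # only the 500 bp SNP
  sr50 <- success_ratios(cpgs, catalog, distances = 50000)
  # distance exactly 50,000 excluded by the strict inequality;
  # the different-chromosome SNP never counts
  expect_equal(sr50$successes, 3L)
  # monotone in distance
  srl <- success_ratios(cpgs, catalog, distances = c(1000, 10001, 50000))
  expect_true(all(diff(srl$success_ratio) >= 0))
})

test_that("group comparison matches exact enumeration and known values", {
  r <- compare_groups(c(0.9, 0.8), c(0.1, 0.2))
  expect_equal(r$U, 4)
  expect_equal(r$p_value, 1 / 6)
  expect_identical(r$method, "exact")
  r2 <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$U, 0)
  expect_equal(r2$p_value, 1)
  r3 <- compare_groups(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r3$U, 9)
  expect_equal(r3$p_value, 0.05)
  expect_error(compare_groups(numeric(0), 1), "non-empty")
})

test_that("exact Mann-Whitney agrees with the null U distribution", {
  for (s in 1:15) {
    withr::with_seed(s, {
      n1 <- sample(2:6, 1); n2 <- sample(2:(10 - n1), 1)
      a <- rnorm(n1); b <- rnorm(n2)  # continuous: no ties
      got <- compare_groups(a, b)
      expect_equal(got$p_value, mw_pwilcox_oracle(a, b), tolerance = 1e-12)
    })
  }
  # swapping groups and direction leaves p invariant
  withr::with_seed(99, {
    a <- runif(5); b <- runif(4)
    expect_equal(compare_groups(a, b, "greater")$p_value,
                 compare_groups(b, a, "less")$p_value)
  })
})

test_that("large-sample Mann-Whitney matches the corrected normal test", {
  withr::with_seed(7, {
    a <- round(runif(25), 2)  # duplicates force the tie correction
    b <- round(runif(30), 2)
    got <- compare_groups(a, b)
    expect_identical(got$method, "normal")
    ref <- wilcox.test(a, b, alternative = "greater", exact = FALSE,
                       correct = TRUE)
    expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-10)
  })
})

test_that("per-locus Fisher enrichment matches tail enumeration", {
  # relevant 10 SNPs, 6 within D; control 100 SNPs, 5 within D
  cpg <- data.frame(cpg_id = "cg1", chromosome = "1", position = 1e6,
                    gene = "GENE1")
  near_rel <- seq(1e6 - 500, by = 100, length.out = 6)
  far_rel <- seq(5e6, by = 1e5, length.out = 4)
  near_con <- seq(1e6 + 100, by = 150, length.out = 5)
  far_con <- seq(3e6, by = 5e4, length.out = 95)
  catalog <- data.frame(
    snp_id = sprintf("rs%03d", 1:110), chromosome = "1",
    position = c(near_rel, far_rel, near_con, far_con),
    pvalue = 1e-8,
    group = c(rep("R", 10), rep("C", 100)), stringsAsFactors = FALSE)
  enr <- locus_enrichment(cpg, catalog, "R", "C", distances = 10000)
  expect_equal(enr$relevant_within, 6L)
  expect_equal(enr$control_within, 5L)
  expect_equal(enr$p_value, fisher_tail_oracle(6, 10, 100, 11),
               tolerance = 1e-12)
  ft <- fisher.test(matrix(c(6, 4, 5, 95), 2, byrow = TRUE),
                    alternative = "greater")
  expect_equal(enr$p_value, unname(ft$p.value), tolerance = 1e-10)
  # all-relevant-within extreme: p = C(3,3)C(5,0)/C(8,3) = 1/56
  expect_equal(fisher_tail_oracle(3, 3, 5, 3), 1 / 56)
  # zero successes in both groups is no evidence
  far_only <- catalog[catalog$position > 2e6, ]
  enr0 <- locus_enrichment(cpg, far_only, "R", "C", distances = 1000)
  expect_equal(enr0$p_value, 1)
})

test_that("locus summary reports the largest significant distance", {
  enr <- data.frame(
    cpg_id = rep(c("a", "b"), each = 3),
    gene = rep(c("GA", "GB"), each = 3),
    max_distance = rep(c(1000, 10000, 50000), 2),
    p_value = c(0.001, 0.002, 0.2, 0.5, 0.6, 0.7),
    fdr = c(0.01, 0.04, 0.4, 0.9, 0.9, 0.9), stringsAsFactors = FALSE)
  best <- locus_max_distance(enr)
  expect_equal(best$cpg_id, "a")
  expect_equal(best$max_distance, 10000)
  expect_equal(nrow(locus_max_distance(enr, fdr_threshold = 0.001)), 0)
})

test_that("log2 success-ratio histograms count CpGs per bin", {
  sr <- data.frame(group = "A", max_distance = 1000,
                   success_ratio = c(0.5, 0.5, 0.25, 0, NA))
  h <- success_ratio_histogram(sr)
  expect_equal(sum(h$count), 3)  # zero and NA ratios dropped
  expect_equal(h$count[h$bin_mid == -0.5], 2)
})
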