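test_that("noiseless covariate relationships are recovered exactly", {
  co <- toy_cohort(15, seed = 10)
  y <- 1 + 0.2 * co$ic50 + 0.001 * co$cigarettes_total +
    0.0005 * co$ic50 * co$cigarettes_total + 0.01 * co$age
  fit <- fit_interaction_model(y, co)
  expect_equal(fit$coefficient,
               c(0.2, 0.001, 0.0005), tolerance = 1e-9)
})

test_that("single-probe fits match the normal-equations oracle", {
  for (s in 1:25) {
    withr::with_seed(s, {
      n <- sample(10:30, 1)
      co <- generate_cohort(n, seed = s * 3 + 1)
      k <- sample(0:3, 1)
      comps <- if (k > 0) {
        m <- matrix(rnorm(n * k), n, k,
                    dimnames = list(co$sample_id, paste0("PC", 1:k)))
        m
      } else NULL
      y <- rnorm(n)
      fit <- fit_interaction_model(y, co, comps)
      X <- cbind(1, co$ic50, co$cigarettes_total,
                 co$ic50 * co$cigarettes_total, co$age)
      if (k > 0) X <- cbind(X, comps)
      ora <- ols_oracle(y, X)
      expect_equal(fit$coefficient, unname(ora$coef[2:4]), tolerance = 1e-10)
      expect_equal(fit$t_value, unname(ora$t[2:4]), tolerance = 1e-10)
      expect_equal(fit$p_value, unname(ora$p[2:4]), tolerance = 1e-10)
    })
  }
})

test_that("degenerate and rank-deficient designs are handled", {
  co <- toy_cohort(12, seed = 11)
  fit <- fit_interaction_model(rep(3, 12), co)
  expect_equal(fit$coefficient, c(0, 0, 0))
  expect_equal(fit$p_value, c(1, 1, 1))
  co0 <- co
  co0$cigarettes_total <- 0  # all never-smokers: smoking column is zero
  expect_error(fit_interaction_model(rnorm(12), co0), "rank deficient")
})

test_that("BH adjustment honours an external total test count", {
  # worked example: the printed top-list against the full test count
  expect_equal(bh_fdr(4.27e-06, 683408), min(1, 683408 * 4.27e-06))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_fdr(c(0.1, 0.2), m_total = 1), "m_total")
  expect_error(bh_fdr(c(0, 0.1)), "0, 1")
  # brute-force oracle and stats::p.adjust agreement on random lists
  for (s in 1:10) {
    withr::with_seed(s, {
      p <- runif(sample(1:20, 1))
      m_tot <- length(p) + sample(0:50, 1)
      expect_equal(bh_fdr(p, m_tot), bh_oracle(p, m_tot), tolerance = 1e-12)
      expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-12)
    })
  }
})

test_that("BH output is permutation-invariant and monotone in p", {
  withr::with_seed(4, {
    p <- runif(50)
    adj <- bh_fdr(p, 200)
    perm <- sample(50)
    expect_equal(bh_fdr(p[perm], 200), adj[perm], tolerance = 1e-14)
    o <- order(p)
    expect_true(all(diff(adj[o]) >= 0))
    expect_true(all(adj > 0 & adj <= 1))
  })
})

test_that("significance tiers follow the FDR-then-p rule", {
  expect_equal(classify_significance(4.27e-06, 0.049), "genome_wide")
  expect_equal(classify_significance(5e-06, 0.2), "suggestive")
  expect_equal(classify_significance(0.5, 0.9), "none")
  expect_equal(classify_significance(c(1e-7, 1e-6, 0.2), c(0.3, 0.01, 0.8)),
               c("suggestive", "genome_wide", "none"))
})

test_that("run_ewas conserves probes and validates its inputs", {
  co <- toy_cohort(20, seed = 12)
  sim <- generate_methylome(co, 30, 2, noise_sd = 0.1, seed = 13)
  beta <- compute_beta(sim$intensities)
  m <- beta_to_m(beta)
  res <- run_ewas(m, co, annotation = sim$annotation)
  expect_equal(nrow(res), 30)
  expect_true(all(c("interaction_p", "interaction_fdr", "chromosome",
                    "position", "gene") %in% names(res)))
  expect_error(run_ewas(beta, co), "M-value")
  m_bad <- m
  colnames(m_bad)[1] <- "stranger"
  expect_error(run_ewas(m_bad, co), "sample mismatch")
})

test_that("plot tables use the i/(m+1) QQ convention and consistent tiers", {
  co <- toy_cohort(25, seed = 14)
  sim <- generate_methylome(co, 3, 1, noise_sd = 0.2, seed = 15)
  m <- beta_to_m(compute_beta(sim$intensities))
  res <- run_ewas(m, co, annotation = sim$annotation)
  pt <- plot_tables(res)
  expect_equal(pt$qq$expected, -log10(c(0.25, 0.5, 0.75)))
  expect_equal(pt$qq$observed, sort(-log10(res$interaction_p),
                                    decreasing = TRUE))
  expect_equal(pt$volcano$tier,
               classify_significance(res$interaction_p,
                                     res$interaction_fdr))
  expect_equal(nrow(pt$manhattan), 3)
})

test_that("uniform p-values sit near the QQ diagonal", {
  co <- generate_cohort(50, seed = 16)
  sim <- generate_methylome(co, 2000, 1, noise_sd = 0.1, seed = 17,
                            config = methylome_config(informative_frac = 0))
  m <- beta_to_m(compute_beta(sim$intensities))
  res <- run_ewas(m, co)
  pt <- plot_tables(res)
  # KS-style bound on uniform order statistics at m = 2000
  ecdf_dev <- max(abs(10^(-pt$qq$observed) -
                        10^(-pt$qq$expected)))
  expect_lt(ecdf_dev, 1.63 / sqrt(2000) * 1.5)
})
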