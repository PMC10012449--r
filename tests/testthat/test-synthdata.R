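test_that("cohort generation respects configured bounds and mixtures", {
  co <- generate_cohort(34, seed = 1)
  expect_equal(nrow(co), 34)
  expect_true(all(co$age >= 40 & co$age <= 66))
  expect_true(all(co$cigarettes_total >= 0 & co$cigarettes_total <= 268800))
  expect_true(all(co$ic50 >= 0.061 & co$ic50 <= 9.49))
  expect_true(all(co$cigarettes_total[co$smoker_class == "never"] == 0))
  expect_true(all(co$cigarettes_total[co$smoker_class != "never"] > 0))
  expect_false(anyDuplicated(co$sample_id) > 0)

  # seeded reproducibility
  expect_identical(co, generate_cohort(34, seed = 1))
  # forced never-smoker fraction
  all_never <- generate_cohort(
    10, cohort_config(smoker_mix = c(never = 1, past = 0, current = 0)),
    seed = 2)
  expect_true(all(all_never$cigarettes_total == 0))
  expect_error(generate_cohort(1), "n_samples")
  expect_error(cohort_config(ic50_sdlog = 0), "degenerate")
})

test_that("methylome composition is exactly invertible through beta/M", {
  co <- toy_cohort(10)
  sim <- generate_methylome(co, 50, 3, noise_sd = 0.05, seed = 3)
  expect_s3_class(sim$intensities, "intensity_table")
  # Dirichlet rows sum to one
  expect_true(all(abs(rowSums(sim$truth$cell_proportions) - 1) < 1e-12))
  expect_true(all(sim$truth$cell_proportions >= 0))
  # intensities non-negative, betas strictly inside (0,1)
  expect_true(all(sim$intensities$m_signal >= 0))
  expect_true(all(sim$intensities$u_signal >= 0))
  beta <- compute_beta(sim$intensities)
  expect_true(all(beta > 0 & beta < 1))
  # round trip beta -> M -> beta
  m <- beta_to_m(beta)
  expect_lt(max(abs(m_to_beta(m) - beta)), 1e-9)
  # determinism
  sim2 <- generate_methylome(co, 50, 3, noise_sd = 0.05, seed = 3)
  expect_identical(sim$intensities$m_signal, sim2$intensities$m_signal)
})

test_that("noiseless planted effects are recovered exactly by the EWAS fit", {
  co <- toy_cohort(20, seed = 7)
  b3 <- planted_effect_size(co, 8, 0.1) / 10  # small enough: no clipping
  sim <- generate_methylome(
    co, 20, 1,
    effects = list(interaction = data.frame(probe = 2, effect = b3)),
    noise_sd = 0, seed = 5,
    config = methylome_config(baseline_sd = 0.5, informative_frac = 0))
  m <- beta_to_m(compute_beta(sim$intensities))
  res <- run_ewas(m, co)
  expect_equal(res$interaction_coef[2], b3, tolerance = 1e-9)
  # probes with no planted effect have zero interaction coefficient
  expect_lt(max(abs(res$interaction_coef[-2])), 1e-12)
  expect_error(
    generate_methylome(co, 10, 1,
                       effects = list(interaction = data.frame(probe = 11,
                                                               effect = 1))),
    "outside")
  expect_error(generate_methylome(co, 10, 1, noise_sd = -1), "non-negative")
})

test_that("GWAS catalog placement matches the uniform and clustered designs", {
  genome <- data.frame(chromosome = "1", length = 1e7)
  targets <- data.frame(chromosome = "1",
                        position = seq(5e5, 9.5e6, length.out = 20))
  # uniform placement: expected per-CpG success ratio ~ 2D/L
  cat_u <- generate_gwas_catalog(c(A = 2000), clustering = list(),
                                 genome = genome, seed = 11)
  sr <- success_ratios(data.frame(cpg_id = "c1", chromosome = "1",
                                  position = 5e6),
                       cat_u, distances = 50000)
  expect_equal(sr$success_ratio, 2 * 50000 / 1e7,
               tolerance = 3 * sqrt(0.01 * 0.99 / 2000) / 0.01)
  # clustered group has higher mean success ratio at its distance
  cat_c <- generate_gwas_catalog(
    c(A = 200, B = 200), probe_targets = targets,
    clustering = list(A = list(fraction = 0.5, distance = 10000)),
    genome = genome, seed = 12)
  sr2 <- success_ratios(
    data.frame(cpg_id = sprintf("c%d", 1:20), chromosome = "1",
               position = targets$position),
    cat_c, distances = 10000)
  expect_gt(mean(sr2$success_ratio[sr2$group == "A"]),
            mean(sr2$success_ratio[sr2$group == "B"]))
  expect_true(all(cat_c$planted[1:100]))
  # determinism
  expect_identical(cat_c, generate_gwas_catalog(
    c(A = 200, B = 200), probe_targets = targets,
    clustering = list(A = list(fraction = 0.5, distance = 10000)),
    genome = genome, seed = 12))
  expect_error(
    generate_gwas_catalog(c(A = 5),
                          clustering = list(A = list(fraction = 0.5,
                                                     distance = 100))),
    "targets")
})

test_that("gene-set generation plants detectable over-representation", {
  universe <- sprintf("G%03d", 1:200)
  expect_length(generate_gene_sets(0, universe), 0)
  expect_error(generate_gene_sets(3, universe, set_size_range = c(10, 300)),
               "exceeds")
  query <- universe[1:40]
  hits <- vapply(1:100, function(s) {
    sets <- generate_gene_sets(2, universe, set_size_range = c(50, 50),
                               enriched_set = list(genes = query, excess = 3),
                               seed = s)
    ora <- hypergeom_ora(query, sets, universe)
    ora$p_value[ora$set_id == "SET001"] < ora$p_value[ora$set_id == "SET002"]
  }, NA)
  expect_gte(mean(hits), 0.95)
})
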