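test_that("simulation is deterministic and dosages stay in [0,2]", {
  cfg <- tiny_config(seed = 11)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$dosage, p2$dosage)
  expect_true(all(p1$dosage %in% 0:2))

  mq1 <- simulate_mqtl_sumstats(p1, cfg)
  mq2 <- simulate_mqtl_sumstats(p2, cfg)
  expect_identical(mq1$sumstats, mq2$sumstats)
  c1 <- simulate_cohort(p1, mq1$truth, cfg)
  c2 <- simulate_cohort(p2, mq2$truth, cfg)
  expect_identical(c1$genotypes$dosage, c2$genotypes$dosage)
  expect_identical(c1$phenotypes, c2$phenotypes)
})

test_that("allele frequencies respect maf_range up to sampling error", {
  cfg <- simulation_config(n_ref = 2000, n_blocks = 4, snps_per_block = 25,
                           maf_range = c(0.1, 0.4), seed = 5)
  panel <- simulate_panel(cfg)
  af <- colMeans(panel$dosage) / 2
  expect_true(all(af > 0.1 - 0.04 & af < 0.4 + 0.04))
})

test_that("ld_decay controls adjacent-SNP correlation", {
  low <- simulate_panel(simulation_config(n_ref = 2000, n_blocks = 2,
                                          snps_per_block = 20,
                                          ld_decay = 0.01, seed = 2))
  r2 <- function(panel) {
    v <- panel$variants
    sapply(which(diff(v$block) == 0), function(j)
      stats::cor(panel$dosage[, j], panel$dosage[, j + 1])^2)
  }
  expect_lte(mean(r2(low)), 0.05)

  high <- simulate_panel(simulation_config(n_ref = 2000, n_blocks = 2,
                                           snps_per_block = 2,
                                           ld_decay = 0.99, seed = 2))
  expect_true(all(r2(high) > 0.5))
})

test_that("config validation rejects impossible settings", {
  expect_error(simulation_config(n_ref = 0), "positive")
  expect_error(simulation_config(ld_decay = 1), "ld_decay")
  expect_error(simulation_config(maf_range = c(0.4, 0.1)), "maf_range")
  expect_error(simulation_config(causal_per_probe = 50, snps_per_block = 10),
               "causal_per_probe")
})

test_that("null mQTL summary statistics give uniform p-values", {
  cfg <- simulation_config(n_ref = 500, n_blocks = 5, snps_per_block = 20,
                           n_probes = 200, causal_per_probe = 1,
                           effect_sd = 0, seed = 42)
  panel <- simulate_panel(cfg)
  ss <- simulate_mqtl_sumstats(panel, cfg)$sumstats
  # one p-value per probe keeps the KS sample effectively independent
  first <- ss[!duplicated(ss$probe), ]
  expect_gt(stats::ks.test(first$pval, "punif")$p.value, 0.01)
})

test_that("a strongly causal SNP is usually the block's top hit", {
  hits <- vapply(1:30, function(i) {
    cfg <- simulation_config(n_ref = 2000, n_blocks = 1, snps_per_block = 15,
                             n_probes = 1, causal_per_probe = 1, seed = 100 + i)
    panel <- simulate_panel(cfg)
    mq <- simulate_mqtl_sumstats(panel, cfg, causal_effects = 1.2)
    top <- mq$sumstats$snp_id[which.min(mq$sumstats$pval)]
    top == mq$truth$causal_snp_ids[[1]]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("marginal beta at an isolated causal SNP is unbiased", {
  est <- vapply(1:500, function(i) {
    cfg <- simulation_config(n_ref = 500, n_blocks = 1, snps_per_block = 8,
                             ld_decay = 0.05, n_probes = 1,
                             causal_per_probe = 1, seed = 2000 + i)
    panel <- simulate_panel(cfg)
    mq <- simulate_mqtl_sumstats(panel, cfg, causal_effects = 0.5)
    mq$sumstats$beta[mq$sumstats$snp_id == mq$truth$causal_snp_ids[[1]]]
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.05 * 0.5)
})

test_that("cohort case fraction and degenerate censoring behave as configured", {
  cfg <- simulation_config(n_ref = 300, n_cohort = 5000, n_blocks = 2,
                           snps_per_block = 10, n_probes = 2,
                           case_fraction = 0.3, seed = 9)
  panel <- simulate_panel(cfg)
  mq <- simulate_mqtl_sumstats(panel, cfg)
  coh <- simulate_cohort(panel, mq$truth, cfg)
  expect_lt(abs(mean(coh$phenotypes$status) - 0.3), 0.03)
  # css_event implies os_event
  ph <- coh$phenotypes[coh$phenotypes$status == 1, ]
  expect_true(all(ph$os_event[ph$css_event == 1] == 1))

  cfg_inf <- simulation_config(n_ref = 300, n_cohort = 500, n_blocks = 2,
                               snps_per_block = 10, n_probes = 2,
                               censor_rate = Inf, seed = 9)
  coh2 <- simulate_cohort(panel, mq$truth, cfg_inf)
  ev <- coh2$phenotypes$os_event[coh2$phenotypes$status == 1]
  expect_true(all(ev == 0))
})

test_that("simulate_coloc_pair validates inputs and plants the right structure", {
  cfg <- simulation_config(n_ref = 1500, seed = 21)
  expect_error(simulate_coloc_pair("H9", 20, cfg), "scenario")
  expect_error(simulate_coloc_pair("H4", 5, cfg), "at least 10")
  pr <- simulate_coloc_pair("H4", 21, cfg)
  expect_identical(pr$truth$causal1, pr$truth$causal2)
  z1 <- abs(pr$stats1$beta / pr$stats1$se)
  expect_gt(z1[pr$stats1$snp_id == pr$truth$causal1], 4)
  h3 <- simulate_coloc_pair("H3", 40, cfg)
  expect_true(h3$truth$causal1 != h3$truth$causal2)
})
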