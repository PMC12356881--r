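null_cohort <- function(seed, n_cohort = 1000, ...) {
  cfg <- simulation_config(n_ref = 300, n_cohort = n_cohort, n_blocks = 2,
                           snps_per_block = 10, n_probes = 2, seed = seed, ...)
  panel <- simulate_panel(cfg)
  mq <- simulate_mqtl_sumstats(panel, cfg)
  simulate_cohort(panel, mq$truth, cfg)
}

test_that("logistic fit flags degenerate inputs instead of erroring", {
  coh <- null_cohort(40)
  r <- fit_risk_model(rep(1, nrow(coh$phenotypes)), coh$phenotypes)
  expect_equal(r$flag, "constant_score")
  expect_true(is.na(r$pval))
  ph <- coh$phenotypes
  ph$status <- 1
  r2 <- fit_risk_model(stats::rnorm(nrow(ph)), ph)
  expect_equal(r2$flag, "degenerate_outcome")
})

test_that("permuted scores give uniform p-values under the null", {
  coh <- null_cohort(41)
  set.seed(41)
  pvals <- vapply(1:200, function(i)
    fit_risk_model(stats::rnorm(nrow(coh$phenotypes)), coh$phenotypes)$pval,
    numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("Cox models honour outcome encodings and degenerate cases", {
  coh <- null_cohort(42, n_cohort = 1500, case_fraction = 0.6)
  ph <- coh$phenotypes
  sc <- stats::rnorm(nrow(ph))
  os <- fit_survival_model(sc, ph, outcome = "OS")
  expect_true(os$events_used > 0 && !is.na(os$pval))

  # CSS with every death of other cause -> zero events -> flagged
  ph2 <- ph
  ph2$css_event[ph2$status == 1] <- 0
  css <- fit_survival_model(sc, ph2, outcome = "CSS")
  expect_equal(css$flag, "no_events")

  # doubling follow-up times leaves the Cox estimate unchanged
  ph3 <- ph
  ph3$os_time <- ph3$os_time * 2
  os2 <- fit_survival_model(sc, ph3, outcome = "OS")
  expect_equal(os$estimate, os2$estimate, tolerance = 1e-9)

  # affine rescaling of the score rescales the estimate, not the p-value
  os3 <- fit_survival_model(2 * sc + 5, ph, outcome = "OS")
  expect_equal(os3$estimate, os$estimate / 2, tolerance = 1e-6)
  expect_equal(os3$pval, os$pval, tolerance = 1e-6)
})

test_that("stage-IV subanalysis errors without stage contrast and is null-calibrated", {
  coh <- null_cohort(43, n_cohort = 1200, case_fraction = 0.6)
  ph <- coh$phenotypes
  scores <- matrix(stats::rnorm(nrow(ph) * 10), ncol = 10,
                   dimnames = list(ph$sample_id, paste0("s", 1:10)))
  res <- run_stage4_subanalysis(scores, ph)
  expect_equal(unique(res$outcome), "risk_stage4")
  expect_true(all(res$fdr_pval >= res$pval, na.rm = TRUE))

  ph4 <- ph
  ph4$stage[ph4$status == 1] <- "IV"
  expect_error(run_stage4_subanalysis(scores, ph4), "two stage categories")
})

test_that("a planted stage-IV effect is detected as the top signal", {
  hits <- vapply(1:20, function(i) {
    cfg <- simulation_config(n_ref = 300, n_cohort = 2000, n_blocks = 2,
                             snps_per_block = 10, n_probes = 4,
                             causal_per_probe = 2, effect_sd = 0.8,
                             case_fraction = 0.9, stage4_log_or = 0.8,
                             seed = 500 + i)
    panel <- simulate_panel(cfg)
    mq <- simulate_mqtl_sumstats(panel, cfg)
    coh <- simulate_cohort(panel, mq$truth, cfg)
    ph <- coh$phenotypes
    scores <- sapply(names(mq$truth$causal_snp_ids), function(pb)
      truth_score(coh$genotypes$dosage, panel, coh$truth, pb))
    rownames(scores) <- ph$sample_id
    res <- run_stage4_subanalysis(scores, ph)
    res$score_id[which.min(res$pval)] == coh$truth$causal_score_ids[1]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("BH adjustment matches p.adjust and the textbook oracle", {
  set.seed(44)
  for (i in 1:1000) {
    k <- sample(1:30, 1)
    p <- stats::runif(k)^sample(1:3, 1)
    m <- k + sample(0:100, 1)
    got <- bh_adjust(p, m)
    expect_equal(got, bh_oracle(p, m), tolerance = 1e-12)
  }
  p <- stats::runif(50)
  expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  expect_equal(bh_adjust(0.01, 1), 0.01)
  expect_error(bh_adjust(c(0.1, 0.2), m_total = 1), "m_total")
  expect_error(bh_adjust(c(0, 0.5)), "0,1")
})

test_that("BH output is monotone, dominated by 1, and order-equivariant", {
  set.seed(45)
  p <- stats::runif(40)
  adj <- bh_adjust(p, 100)
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(adj <= 1))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
  perm <- sample(40)
  expect_equal(bh_adjust(p[perm], 100), adj[perm])
})

test_that("Bonferroni thresholds reproduce the worked examples", {
  expect_equal(signif(bonferroni_threshold(0.05, 19), 2), 0.0026)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(signif(bonferroni_threshold(0.05, 118982), 2), 4.2e-7)
  expect_error(bonferroni_threshold(1.5, 10), "alpha")
})

test_that("associate_scores adjusts p-values per outcome family", {
  coh <- null_cohort(46, n_cohort = 800, case_fraction = 0.5)
  ph <- coh$phenotypes
  scores <- matrix(stats::rnorm(nrow(ph) * 5), ncol = 5,
                   dimnames = list(ph$sample_id, paste0("s", 1:5)))
  res <- associate_scores(scores, ph, "risk")
  expect_equal(res$fdr_pval, bh_adjust(res$pval))
  res_m <- associate_scores(scores, ph, "risk", m_total = 1000)
  expect_equal(res_m$fdr_pval, bh_adjust(res$pval, 1000))
  surv <- associate_scores(scores, ph, "OS")
  expect_true(all(surv$outcome == "OS"))
  expect_true(all(surv$fdr_pval >= surv$pval, na.rm = TRUE))
})
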