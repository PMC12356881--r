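test_that("LD matrix construction: unit diagonal, sampling bounds, rank flags", {
  cfg <- simulation_config(n_ref = 5000, n_blocks = 8, snps_per_block = 2,
                           ld_decay = 0.01, seed = 12)
  panel <- simulate_panel(cfg)
  ids <- panel$variants$id[seq(1, 16, by = 2)]   # one SNP per block: independent
  ld <- compute_ld_matrix(panel, ids, ridge = 0)
  off <- ld$R[upper.tri(ld$R)]
  expect_lt(max(abs(off)), 0.05)
  ldr <- compute_ld_matrix(panel, ids, ridge = 0.01)
  expect_equal(unname(diag(ldr$R)), rep(1, length(ids)))

  dup <- panel
  dup$dosage <- cbind(panel$dosage, panel$dosage[, 1])
  dup$variants <- rbind(panel$variants,
                        within(panel$variants[1, ], id <- "dupSNP"))
  dup$dosage[, ncol(dup$dosage)] <- panel$dosage[, 1]
  colnames(dup$dosage) <- dup$variants$id
  ld_dup <- compute_ld_matrix(dup, c(panel$variants$id[1], "dupSNP"), ridge = 0)
  expect_equal(ld_dup$R[1, 2], 1)
  expect_error(compute_score_weights(c(1, 1), ld_dup), "singular|ill-conditioned")

  mono <- panel
  mono$dosage[, 2] <- 1
  expect_error(compute_ld_matrix(mono, panel$variants$id[1:2]),
               panel$variants$id[2])
})

test_that("weight solve handles identity, scalar and the 3x3 hand-solved system", {
  expect_equal(compute_score_weights(c(1, -2, 3), diag(3)), c(1, -2, 3))
  expect_equal(compute_score_weights(0.7, matrix(1, 1, 1)), 0.7)
  R <- rbind(c(1, .5, 0), c(.5, 1, 0), c(0, 0, 1))
  # by elimination: w1 = w2 = 2/3, w3 = 2
  expect_equal(compute_score_weights(c(1, 1, 2), R), c(2/3, 2/3, 2),
               tolerance = 1e-12)
})

make_scored_dataset <- function(seed = 30, ...) {
  cfg <- simulation_config(n_ref = 600, n_cohort = 800, n_blocks = 4,
                           snps_per_block = 20, n_probes = 4,
                           causal_per_probe = 2, effect_sd = 0.6,
                           seed = seed, ...)
  panel <- simulate_panel(cfg)
  mq <- simulate_mqtl_sumstats(panel, cfg)
  coh <- simulate_cohort(panel, mq$truth, cfg)
  harm <- harmonize_alleles(mq$sumstats, panel, coh$genotypes)
  regions <- unlist(lapply(split(harm$sumstats, harm$sumstats$probe),
                           partition_regions), recursive = FALSE)
  defs <- build_score_definitions(regions, harm$sumstats, harm$panel)
  list(cfg = cfg, panel = panel, mq = mq, coh = coh, harm = harm,
       regions = regions, defs = defs)
}

test_that("score computation is linear and matches a brute-force loop", {
  d <- make_scored_dataset()
  expect_gt(length(d$defs), 0)
  scores <- compute_scores(d$harm$cohort, d$defs)

  # brute force: explicit per-sample, per-SNP accumulation
  def <- d$defs[[1]]
  manual <- vapply(seq_len(nrow(d$harm$cohort$dosage)), function(i) {
    s <- 0
    for (k in seq_along(def$snp_ids))
      s <- s + d$harm$cohort$dosage[i, def$snp_ids[k]] * def$weights[k]
    s
  }, numeric(1))
  expect_equal(unname(scores$values[, def$score_id]), manual, tolerance = 1e-12)

  # all dosages zero -> zero scores
  zero <- d$harm$cohort
  zero$dosage[] <- 0
  expect_true(all(compute_scores(zero, d$defs)$values == 0))

  # doubling betas doubles the score column
  defs2 <- d$defs
  defs2[[1]]$betas <- 2 * defs2[[1]]$betas
  defs2[[1]]$weights <- compute_score_weights(defs2[[1]]$betas, defs2[[1]]$ld)
  s2 <- compute_scores(d$harm$cohort, defs2)
  expect_equal(s2$values[, 1], 2 * scores$values[, 1], tolerance = 1e-10)
})

test_that("missing cohort SNPs are dropped and weights re-solved", {
  d <- make_scored_dataset(seed = 31)
  def <- d$defs[[1]]
  cut <- d$harm$cohort
  drop_id <- def$snp_ids[1]
  keep <- cut$variants$id != drop_id
  cut$dosage <- cut$dosage[, keep, drop = FALSE]
  cut$variants <- cut$variants[keep, , drop = FALSE]
  s <- compute_scores(cut, list(def))
  kept_def <- s$defs[[def$score_id]]
  expect_false(drop_id %in% kept_def$snp_ids)
  expect_equal(length(kept_def$weights), length(def$snp_ids) - 1)
  # re-solved against the subset LD matrix, not zero-imputed
  expect_equal(kept_def$weights,
               compute_score_weights(kept_def$betas, kept_def$ld))
})

test_that("distance classification follows the cis / cis-x / trans thresholds", {
  genes <- data.frame(gene = "G1", chrom = "1", start = 1e6, end = 2e6)
  pg <- data.frame(probe = "cg1", gene = "G1")
  mk <- function(chrom, start, end)
    list(probe_id = "cg1", chrom = chrom, start = start, end = end)
  expect_equal(classify_score(mk("1", 1.5e6, 1.6e6), genes, pg), "cis")   # overlap
  expect_equal(classify_score(mk("1", 2e6 + 49999, 2.1e6), genes, pg), "cis")
  expect_equal(classify_score(mk("1", 3e6, 3.1e6), genes, pg), "cis-x")   # 1 Mb gap
  expect_equal(classify_score(mk("1", 2e6 + 50000, 2.2e6), genes, pg), "cis-x")
  expect_equal(classify_score(mk("1", 8e6, 8.1e6), genes, pg), "trans")
  expect_equal(classify_score(mk("5", 1.5e6, 1.6e6), genes, pg), "trans")
  expect_equal(classify_score(list(probe_id = "cgX", chrom = "1",
                                   start = 1, end = 2), genes, pg),
               "unclassified")
})

test_that("correlated scores are pruned most-significant-first", {
  d <- make_scored_dataset(seed = 32)
  scores <- compute_scores(d$harm$cohort, d$defs)
  # duplicate the most significant score under another id
  dup <- scores
  best <- names(which.min(vapply(scores$defs, `[[`, numeric(1), "min_pval")))
  dup$values <- cbind(scores$values, dup_col = scores$values[, best])
  colnames(dup$values)[ncol(dup$values)] <- "dup_col"
  dcopy <- scores$defs[[best]]
  dcopy$score_id <- "dup_col"
  dcopy$min_pval <- dcopy$min_pval * 10
  dup$defs$dup_col <- dcopy
  pr <- prune_correlated_scores(dup, 0.90)
  expect_true(best %in% colnames(pr$scores$values))
  expect_false("dup_col" %in% colnames(pr$scores$values))
  expect_equal(pr$dropped$displaced_by, best)
  # no remaining pair exceeds the threshold
  live <- pr$scores$values[, apply(pr$scores$values, 2, stats::sd) > 0,
                           drop = FALSE]
  if (ncol(live) > 1) {
    cc <- abs(stats::cor(live))
    expect_lte(max(cc[upper.tri(cc)]), 0.90)
  }
})

test_that("independent scores survive pruning at the default threshold", {
  d <- make_scored_dataset(seed = 33)
  # one score per block: mutually independent by construction
  scores <- compute_scores(d$harm$cohort, d$defs)
  one_per_block <- !duplicated(vapply(scores$defs, `[[`, character(1), "chrom"))
  sub <- scores
  sub$values <- scores$values[, one_per_block, drop = FALSE]
  sub$defs <- scores$defs[one_per_block]
  pr <- prune_correlated_scores(sub, 0.90)
  expect_equal(ncol(pr$scores$values), ncol(sub$values))
  expect_equal(nrow(pr$dropped), 0)
})

test_that("HLA exclusion removes only chr6 SNPs inside the span", {
  ss <- data.frame(probe = "cg1", chrom = c("6", "6", "7"),
                   pos = c(26e6, 36e6, 26e6), effect_allele = "G",
                   other_allele = "A", beta = 1, se = 1, pval = 0.5,
                   snp_id = c("a", "b", "c"))
  out <- exclude_hla(ss)
  expect_setequal(out$snp_id, c("b", "c"))
  expect_identical(exclude_hla(ss, NULL), ss)
})

test_that("consistent allele flips shift scores by a constant and leave tests unchanged", {
  d <- make_scored_dataset(seed = 35, score_log_or = 0.4)
  flip_id <- d$defs[[1]]$snp_ids[2]
  j <- which(d$panel$variants$id == flip_id)

  flip_geno <- function(g) {
    g$dosage[, j] <- 2 - g$dosage[, j]
    g$variants[j, c("ref", "alt")] <- g$variants[j, c("alt", "ref")]
    g
  }
  ss2 <- d$mq$sumstats
  k <- ss2$snp_id == flip_id
  ss2[k, c("effect_allele", "other_allele")] <- ss2[k, c("other_allele", "effect_allele")]
  ss2$beta[k] <- -ss2$beta[k]

  harm2 <- harmonize_alleles(ss2, flip_geno(d$panel), flip_geno(d$coh$genotypes))
  defs2 <- build_score_definitions(d$regions, harm2$sumstats, harm2$panel)
  s1 <- compute_scores(d$harm$cohort, d$defs)
  s2 <- compute_scores(harm2$cohort, defs2)
  shift <- s2$values[, 1] - s1$values[, 1]
  expect_lt(stats::sd(shift), 1e-8)   # additive constant only

  r1 <- fit_risk_model(s1$values[, 1], d$coh$phenotypes)
  r2 <- fit_risk_model(s2$values[, 1], d$coh$phenotypes)
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-6)
  expect_equal(r1$pval, r2$pval, tolerance = 1e-6)
})

test_that("ridge 0 reproduces the exact solve on well-conditioned regions", {
  d <- make_scored_dataset(seed = 36)
  def <- d$defs[[1]]
  ld0 <- compute_ld_matrix(d$harm$panel, def$snp_ids, ridge = 0)
  w0 <- compute_score_weights(def$betas, ld0)
  expect_equal(unname(drop(solve(ld0$R) %*% def$betas)), w0, tolerance = 1e-8)
  # association varies continuously in the ridge parameter
  wr <- compute_score_weights(def$betas, compute_ld_matrix(d$harm$panel,
                                                           def$snp_ids,
                                                           ridge = 1e-4))
  expect_lt(max(abs(wr - w0)) / max(abs(w0)), 0.05)
})
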