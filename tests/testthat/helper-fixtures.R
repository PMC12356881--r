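# shared fixtures and independent oracles used across test files

tiny_config <- function(seed = 1L, ...) {
  simulation_config(n_ref = 400, n_cohort = 600, n_blocks = 3,
                    snps_per_block = 20, n_probes = 3, causal_per_probe = 1,
                    effect_sd = 0.5, seed = seed, ...)
}

# standardised genetic value of a probe, recomputed from recorded ground
# truth only (panel moments fix the scale)
truth_score <- function(dosage, panel, truth, probe) {
  ids <- truth$causal_snp_ids[[probe]]
  b <- truth$causal_effect_sizes[[probe]]
  ref <- drop(panel$dosage[, ids, drop = FALSE] %*% b)
  (drop(dosage[, ids, drop = FALSE] %*% b) - mean(ref)) / stats::sd(ref)
}

# textbook step-up BH oracle: explicit double loop over ranks
bh_oracle <- function(p, m_total = length(p)) {
  k <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(k)
  for (j in seq_len(k)) {
    vals <- vapply(j:k, function(h) ps[h] * m_total / h, numeric(1))
    adj[j] <- min(1, min(vals))
  }
  out <- numeric(k)
  out[o] <- adj
  out
}

# single-linkage clustering oracle built from the full pairwise adjacency
# graph (not the consecutive-gap recurrence the implementation uses)
partition_oracle <- function(df, p_seed, p_include, min_sep) {
  df <- df[df$pval < p_include, , drop = FALSE]
  if (!nrow(df)) return(list())
  out <- list()
  for (ch in unique(df$chrom)) {
    dc <- df[df$chrom == ch, , drop = FALSE]
    n <- nrow(dc)
    adj <- abs(outer(dc$pos, dc$pos, "-")) < min_sep
    comp <- seq_len(n)
    repeat {
      new <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), numeric(1))
      if (identical(new, comp)) break
      comp <- new
    }
    for (g in split(seq_len(n), comp)) {
      if (!any(dc$pval[g] < p_seed)) next
      out[[length(out) + 1L]] <- list(chrom = ch, start = min(dc$pos[g]),
                                      end = max(dc$pos[g]),
                                      snp_ids = sort(dc$snp_id[g]))
    }
  }
  out
}

# naive (non-log) five-hypothesis posterior for small instances
coloc_oracle <- function(stats1, stats2, cfg, sd1, sd2) {
  common <- intersect(stats1$snp_id, stats2$snp_id)
  s1 <- stats1[match(common, stats1$snp_id), ]
  s2 <- stats2[match(common, stats2$snp_id), ]
  abf <- function(b, se, sd0) {
    r <- sd0^2 / (sd0^2 + se^2)
    sqrt(1 - r) * exp(r * (b / se)^2 / 2)
  }
  a1 <- abf(s1$beta, s1$se, sd1)
  a2 <- abf(s2$beta, s2$se, sd2)
  S1 <- sum(a1); S2 <- sum(a2); S12 <- sum(a1 * a2)
  w <- c(1, cfg$p1 * S1, cfg$p2 * S2, cfg$p1 * cfg$p2 * (S1 * S2 - S12),
         cfg$p12 * S12)
  stats::setNames(w / sum(w), c("H0", "H1", "H2", "H3", "H4"))
}

random_sumstats <- function(n, chroms = 1:2, pos_max = 5e6) {
  data.frame(probe = "cgTEST", chrom = as.character(sample(chroms, n, TRUE)),
             pos = sample.int(pos_max, n),
             effect_allele = "G", other_allele = "A",
             beta = stats::rnorm(n), se = stats::runif(n, 0.01, 0.2),
             pval = 10^stats::runif(n, -8, 0),
             snp_id = sprintf("s%04d", seq_len(n)), stringsAsFactors = FALSE)
}
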