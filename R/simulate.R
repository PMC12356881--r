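#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator: reference-panel
#' and cohort sizes, LD-block genotype structure, per-probe mQTL
#' architecture, planted disease effects and survival/censoring rates.
#' Defaults describe a moderate case-control study: roughly a third of the
#' cohort are cases, follow-up deaths accrue at a baseline hazard of
#' 0.08 per year against independent censoring at 0.04 per year, and about
#' 70 percent of deaths are disease-specific.
#'
#' @param n_ref reference-panel sample count.
#' @param n_cohort cohort sample count.
#' @param n_blocks number of independent LD blocks (one chromosome each).
#' @param snps_per_block SNPs per block.
#' @param ld_decay haplotype-copying probability in (0,1); adjacent-SNP LD
#'   rises with this value.
#' @param maf_range lower/upper bounds for simulated allele frequencies,
#'   within (0, 0.5].
#' @param pos_spacing base-pair spacing between adjacent SNPs (1-based
#'   coordinates start at `pos_spacing`).
#' @param n_probes number of methylation probes.
#' @param causal_per_probe causal SNPs per probe (must not exceed
#'   `snps_per_block`).
#' @param effect_sd standard deviation of causal methylation effects.
#' @param case_fraction target case proportion in the cohort.
#' @param score_log_or planted log odds ratio per unit (standardised) genetic
#'   score for designated causal probes; 0 plants nothing.
#' @param stage4_log_or planted log odds ratio of stage IV at presentation
#'   per unit score; 0 (default) simulates stage independent of genotype.
#' @param log_hr planted log hazard ratio per unit score for survival and
#'   recurrence.
#' @param baseline_hazard exponential baseline event rate (per year).
#' @param censor_rate exponential censoring rate (per year); 0 disables
#'   censoring, `Inf` censors everything at time zero.
#' @param crc_death_frac fraction of deaths attributed to the disease.
#' @param stage_probs probabilities of AJCC stages I-IV.
#' @param seed integer random seed; identical seed + config gives
#'   byte-identical output.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_ref = 2000, n_cohort = 2000,
                              n_blocks = 5, snps_per_block = 40,
                              ld_decay = 0.9, maf_range = c(0.05, 0.5),
                              pos_spacing = 1000,
                              n_probes = 10, causal_per_probe = 2,
                              effect_sd = 0.3,
                              case_fraction = 0.35,
                              score_log_or = 0, stage4_log_or = 0, log_hr = 0,
                              baseline_hazard = 0.08, censor_rate = 0.04,
                              crc_death_frac = 0.7,
                              stage_probs = c(0.20, 0.35, 0.30, 0.15),
                              seed = 1L) {
  counts <- c(n_ref = n_ref, n_cohort = n_cohort, n_blocks = n_blocks,
              snps_per_block = snps_per_block, n_probes = n_probes,
              causal_per_probe = causal_per_probe, pos_spacing = pos_spacing)
  if (any(counts <= 0)) stop_input("all counts must be positive")
  if (ld_decay <= 0 || ld_decay >= 1) stop_input("ld_decay must lie strictly in (0,1)")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop_input("maf_range must be ordered and within (0, 0.5]")
  if (causal_per_probe > snps_per_block)
    stop_input("causal_per_probe cannot exceed snps_per_block")
  if (case_fraction <= 0 || case_fraction >= 1)
    stop_input("case_fraction must lie in (0,1)")
  structure(list(n_ref = as.integer(n_ref), n_cohort = as.integer(n_cohort),
                 n_blocks = as.integer(n_blocks),
                 snps_per_block = as.integer(snps_per_block),
                 ld_decay = ld_decay, maf_range = maf_range,
                 pos_spacing = as.integer(pos_spacing),
                 n_probes = as.integer(n_probes),
                 causal_per_probe = as.integer(causal_per_probe),
                 effect_sd = effect_sd, case_fraction = case_fraction,
                 score_log_or = score_log_or, stage4_log_or = stage4_log_or,
                 log_hr = log_hr,
                 baseline_hazard = baseline_hazard, censor_rate = censor_rate,
                 crc_death_frac = crc_death_frac, stage_probs = stage_probs,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Genotype matrix container
#'
#' A samples-by-variants dosage matrix (values in \[0,2\]) with variant
#' metadata. Simulated panels additionally carry the per-variant base allele
#' frequency and LD-block label needed to redraw cohorts from the same
#' haplotype process.
#'
#' @param dosage numeric matrix, samples in rows, variants in columns.
#' @param variants data.frame with columns `id, chrom, pos, ref, alt` (and
#'   optionally `freq`, `block`, `info`), one row per column of `dosage`.
#' @param ld_decay haplotype-copying parameter used to generate the panel,
#'   if simulated.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants, ld_decay = NULL) {
  stopifnot(is.matrix(dosage), nrow(variants) == ncol(dosage))
  if (anyDuplicated(variants$id)) stop_input("variant ids must be unique")
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop_input("dosages must lie in [0,2]")
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage, variants = variants,
                 sample_ids = rownames(dosage), ld_decay = ld_decay),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$variants$chrom))))
  invisible(x)
}

# draw 2n haplotypes for one block by first-order copying:
# allele j equals allele j-1 with probability ld_decay, else fresh Bernoulli(f_j)
sim_block_haplotypes <- function(n_hap, freqs, ld_decay) {
  m <- length(freqs)
  H <- matrix(0L, n_hap, m)
  H[, 1] <- stats::rbinom(n_hap, 1, freqs[1])
  if (m > 1) for (j in 2:m) {
    copy <- stats::runif(n_hap) < ld_decay
    fresh <- stats::rbinom(n_hap, 1, freqs[j])
    H[, j] <- ifelse(copy, H[, j - 1], fresh)
  }
  H
}

sim_genotypes <- function(n, variants, ld_decay) {
  blocks <- split(seq_len(nrow(variants)), variants$block)
  cols <- lapply(blocks, function(idx) {
    h1 <- sim_block_haplotypes(n, variants$freq[idx], ld_decay)
    h2 <- sim_block_haplotypes(n, variants$freq[idx], ld_decay)
    h1 + h2
  })
  G <- do.call(cbind, cols)[, order(unlist(blocks, use.names = FALSE)), drop = FALSE]
  storage.mode(G) <- "double"
  G
}

#' Simulate a reference genotype panel
#'
#' Generates haplotypes block by block with a first-order copying process:
#' within a block each successive allele copies the previous haplotype allele
#' with probability `ld_decay`, otherwise it is drawn fresh at its own
#' frequency, producing monotonically decaying LD along the block. Blocks are
#' mutually independent and each block sits on its own chromosome with
#' 1-based positions spaced `pos_spacing` apart.
#'
#' @param config a [simulation_config()].
#' @return a [genotype_matrix()] of `n_ref` samples.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  m <- config$n_blocks * config$snps_per_block
  variants <- data.frame(
    id = sprintf("rs%05d", seq_len(m)),
    chrom = as.character(rep(seq_len(config$n_blocks), each = config$snps_per_block)),
    pos = rep(seq_len(config$snps_per_block), config$n_blocks) * config$pos_spacing,
    ref = "A", alt = "G",
    freq = stats::runif(m, config$maf_range[1], config$maf_range[2]),
    block = rep(seq_len(config$n_blocks), each = config$snps_per_block),
    info = 1,
    stringsAsFactors = FALSE)
  G <- sim_genotypes(config$n_ref, variants, config$ld_decay)
  rownames(G) <- sprintf("ref%05d", seq_len(config$n_ref))
  genotype_matrix(G, variants, ld_decay = config$ld_decay)
}

#' Simulate mQTL summary statistics with recorded ground truth
#'
#' Each probe is assigned to an LD block (cycling over blocks), receives
#' `causal_per_probe` causal SNPs with normal effects, and a quantitative
#' methylation phenotype is synthesised on the panel as the causal linear
#' predictor plus unit-variance noise. Per-SNP marginal OLS over all SNPs in
#' the probe's block yields the exported beta/SE/p-value records, mimicking
#' how meta-analysed cis-mQTL summary statistics arise. A gene span is
#' planted around the centre of each probe's block so distance-based score
#' classification is exercisable.
#'
#' @param panel a simulated [genotype_matrix()].
#' @param config the [simulation_config()] used for the panel.
#' @param causal_effects optional fixed causal effect sizes (recycled to
#'   `causal_per_probe`), overriding the normal draw — convenient for
#'   parameter-recovery studies.
#' @return a list with elements `sumstats` (data.frame with columns
#'   `probe, chrom, pos, effect_allele, other_allele, beta, se, pval, snp_id`),
#'   `genes` (gene spans), `probe_genes` (probe-to-gene map) and `truth`
#'   (per-probe causal SNP ids and effect sizes).
#' @export
simulate_mqtl_sumstats <- function(panel, config, causal_effects = NULL) {
  stopifnot(inherits(panel, "genotype_matrix"))
  set.seed(config$seed + 1L)
  v <- panel$variants
  probes <- sprintf("cg%08d", seq_len(config$n_probes))
  blocks <- ((seq_len(config$n_probes) - 1L) %% config$n_blocks) + 1L
  causal <- stats::setNames(vector("list", config$n_probes), probes)
  effects <- causal
  out <- vector("list", config$n_probes)
  for (i in seq_len(config$n_probes)) {
    idx <- which(v$block == blocks[i])
    ci <- sort(sample(idx, config$causal_per_probe))
    b <- if (is.null(causal_effects))
      stats::rnorm(config$causal_per_probe, 0, config$effect_sd)
    else rep_len(causal_effects, config$causal_per_probe)
    y <- drop(panel$dosage[, ci, drop = FALSE] %*% b) + stats::rnorm(config$n_ref)
    fit <- marginal_ols(panel$dosage[, idx, drop = FALSE], y)
    causal[[i]] <- v$id[ci]
    effects[[i]] <- b
    out[[i]] <- data.frame(probe = probes[i], chrom = v$chrom[idx], pos = v$pos[idx],
                           effect_allele = v$alt[idx], other_allele = v$ref[idx],
                           beta = fit$beta, se = fit$se, pval = fit$pval,
                           snp_id = v$id[idx], stringsAsFactors = FALSE)
  }
  centre <- (config$snps_per_block %/% 2L) * config$pos_spacing
  genes <- data.frame(gene = sprintf("GENE%d", seq_len(config$n_blocks)),
                      chrom = as.character(seq_len(config$n_blocks)),
                      start = pmax(1L, centre - 10000L), end = centre + 10000L,
                      stringsAsFactors = FALSE)
  truth <- list(causal_snp_ids = causal, causal_effect_sizes = effects,
                probe_block = stats::setNames(blocks, probes),
                causal_score_ids = character(0),
                planted_log_or = numeric(0), planted_log_hr = numeric(0),
                coloc_scenarios = character(0))
  list(sumstats = do.call(rbind, out),
       genes = genes,
       probe_genes = data.frame(probe = probes,
                                gene = genes$gene[blocks],
                                stringsAsFactors = FALSE),
       truth = truth)
}

# per-sample standardised genetic value of a probe (panel moments fix the scale)
probe_genetic_value <- function(dosage, panel, truth, probe) {
  ids <- truth$causal_snp_ids[[probe]]
  b <- truth$causal_effect_sizes[[probe]]
  raw_panel <- drop(panel$dosage[, ids, drop = FALSE] %*% b)
  s <- stats::sd(raw_panel)
  if (s == 0) s <- 1
  (drop(dosage[, ids, drop = FALSE] %*% b) - mean(raw_panel)) / s
}

#' Simulate a cohort with planted disease effects
#'
#' Cohort genotypes are drawn from the same haplotype-copying process as the
#' panel. Case-control status follows a logistic model whose linear predictor
#' is `score_log_or` times the standardised genetic value of each designated
#' causal probe, with the intercept tuned numerically so the expected case
#' proportion equals `case_fraction`. Survival and recurrence times for
#' cases are exponential with hazard multiplied by `exp(log_hr * value)`,
#' independently censored at `censor_rate`; the disease is recorded as cause
#' of death for a `crc_death_frac` share of deaths. Age, sex, ten principal
#' component covariates and AJCC stage are simulated independently of
#' genotype.
#'
#' @param panel a simulated [genotype_matrix()].
#' @param truth ground-truth list from [simulate_mqtl_sumstats()]; its
#'   `causal_score_ids`, `planted_log_or` and `planted_log_hr` fields are
#'   filled in by this function.
#' @param config the [simulation_config()].
#' @param causal_probes probes whose genetic values drive the outcome;
#'   defaults to the first probe when `score_log_or` or `log_hr` is non-zero.
#' @return a list with `genotypes` (a [genotype_matrix()]), `phenotypes`
#'   (data.frame) and the updated `truth`.
#' @export
simulate_cohort <- function(panel, truth, config, causal_probes = NULL) {
  stopifnot(inherits(panel, "genotype_matrix"))
  set.seed(config$seed + 2L)
  has_effect <- config$score_log_or != 0 || config$log_hr != 0 ||
    config$stage4_log_or != 0
  if (is.null(causal_probes) && has_effect)
    causal_probes <- names(truth$causal_snp_ids)[1]
  if (has_effect && !length(causal_probes))
    stop_input("non-zero planted effect requires at least one causal probe")
  n <- config$n_cohort
  G <- sim_genotypes(n, panel$variants, panel$ld_decay %||% config$ld_decay)
  rownames(G) <- sprintf("s%05d", seq_len(n))
  geno <- genotype_matrix(G, panel$variants, ld_decay = panel$ld_decay)

  lp_or <- lp_hr <- lp_s4 <- rep(0, n)
  for (pb in causal_probes) {
    z <- probe_genetic_value(geno$dosage, panel, truth, pb)
    lp_or <- lp_or + config$score_log_or * z
    lp_hr <- lp_hr + config$log_hr * z
    lp_s4 <- lp_s4 + config$stage4_log_or * z
  }
  alpha <- stats::uniroot(function(a) mean(stats::plogis(a + lp_or)) - config$case_fraction,
                          c(-30, 30))$root
  status <- stats::rbinom(n, 1, stats::plogis(alpha + lp_or))

  age <- round(ifelse(status == 1, stats::rnorm(n, 63, 12), stats::rnorm(n, 59, 12)))
  sex <- stats::rbinom(n, 1, ifelse(status == 1, 0.57, 0.46))
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))
  # stage drawn in two steps so dependence on genotype is configurable:
  # IV vs not by a logistic tilt of the marginal stage-IV probability, then
  # I-III at their renormalised marginal probabilities
  stage <- rep(NA_character_, n)
  ncase <- sum(status)
  p4 <- stats::plogis(stats::qlogis(config$stage_probs[4]) + lp_s4[status == 1])
  is4 <- stats::rbinom(ncase, 1, p4) == 1
  stage123 <- sample(c("I", "II", "III"), ncase, replace = TRUE,
                     prob = config$stage_probs[1:3])
  stage[status == 1] <- ifelse(is4, "IV", stage123)

  os_time <- css_event <- os_event <- rfs_time <- rfs_event <- rep(NA_real_, n)
  if (ncase > 0) {
    draw_surv <- function(rate_mult) {
      ev_t <- stats::rexp(ncase) / (config$baseline_hazard * rate_mult)
      cn_t <- if (config$censor_rate == 0) rep(Inf, ncase)
              else if (is.infinite(config$censor_rate)) rep(0, ncase)
              else stats::rexp(ncase, config$censor_rate)
      list(time = pmin(ev_t, cn_t), event = as.numeric(ev_t <= cn_t & cn_t > 0))
    }
    mult <- exp(lp_hr[status == 1])
    os <- draw_surv(mult)
    os_time[status == 1] <- os$time
    os_event[status == 1] <- os$event
    crc_cause <- stats::rbinom(ncase, 1, config$crc_death_frac)
    css_event[status == 1] <- os$event * crc_cause
    rfs <- draw_surv(mult)
    rfs_time[status == 1] <- rfs$time
    rfs_event[status == 1] <- rfs$event
  }
  phen <- data.frame(sample_id = rownames(G), status = status, age = age, sex = sex,
                     pcs, stage = stage,
                     os_time = os_time, os_event = os_event, css_event = css_event,
                     rfs_time = rfs_time, rfs_event = rfs_event,
                     stringsAsFactors = FALSE)
  truth$causal_score_ids <- causal_probes %||% character(0)
  truth$planted_log_or <- rep(config$score_log_or, length(truth$causal_score_ids))
  truth$planted_log_hr <- rep(config$log_hr, length(truth$causal_score_ids))
  list(genotypes = geno, phenotypes = phen, truth = truth)
}

#' Simulate a pair of regional summary statistics for colocalisation
#'
#' Generates one LD block and two independent cohorts of `n_ref` samples
#' drawn from it, then two quantitative traits whose causal configuration is
#' set by `scenario`: `H0` no causal variant in either trait, `H1`/`H2` a
#' causal variant in one trait only, `H3` two distinct causal variants (the
#' first and last SNP of the block, far enough apart that their LD is
#' negligible), `H4` a single shared causal variant at the block centre.
#' Causal effect sizes are chosen so the causal SNP's expected marginal
#' z-score equals `z_causal`.
#'
#' @param scenario one of `"H0".."H4"`.
#' @param n_snps number of SNPs in the region (at least 10).
#' @param config a [simulation_config()]; `n_ref`, `ld_decay`, `maf_range`
#'   and `seed` are used.
#' @param z_causal target absolute z-score at causal SNPs.
#' @return list with `stats1`, `stats2` (data.frames `snp_id, chrom, pos,
#'   beta, se, pval`) and `truth` (scenario label and causal SNP ids).
#' @export
simulate_coloc_pair <- function(scenario, n_snps, config, z_causal = 8) {
  if (!scenario %in% c("H0", "H1", "H2", "H3", "H4"))
    stop_input("unknown scenario label: ", scenario)
  if (n_snps < 10) stop_input("n_snps must be at least 10")
  set.seed(config$seed + 3L)
  freqs <- stats::runif(n_snps, config$maf_range[1], config$maf_range[2])
  variants <- data.frame(id = sprintf("rs%05d", seq_len(n_snps)), chrom = "1",
                         pos = seq_len(n_snps) * config$pos_spacing,
                         freq = freqs, block = 1L)
  causal1 <- causal2 <- integer(0)
  mid <- (n_snps + 1L) %/% 2L
  if (scenario == "H1") causal1 <- mid
  if (scenario == "H2") causal2 <- mid
  if (scenario == "H3") { causal1 <- 1L; causal2 <- n_snps }
  if (scenario == "H4") causal1 <- causal2 <- mid

  one_trait <- function(causal) {
    G <- sim_genotypes(config$n_ref, variants, config$ld_decay)
    y <- stats::rnorm(config$n_ref)
    if (length(causal)) {
      sdg <- sqrt(2 * freqs[causal] * (1 - freqs[causal]))
      b <- z_causal / (sdg * sqrt(config$n_ref))
      y <- y + drop(G[, causal, drop = FALSE] %*% b)
    }
    cbind(variants[c("id", "chrom", "pos")], marginal_ols(G, y))
  }
  s1 <- one_trait(causal1); names(s1)[1] <- "snp_id"
  s2 <- one_trait(causal2); names(s2)[1] <- "snp_id"
  list(stats1 = s1, stats2 = s2,
       truth = list(scenario = scenario,
                    causal1 = variants$id[causal1],
                    causal2 = variants$id[causal2]))
}
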