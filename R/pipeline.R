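#' Helper principal components for synthetic genotypes
#'
#' Thin wrapper around [stats::prcomp()] on centred dosages, supplying
#' ancestry-style covariates for simulated cohorts. Not intended for
#' cohort-scale real data, where externally computed PCs are expected as
#' phenotype-table columns.
#'
#' @param g a [genotype_matrix()].
#' @param n_pc number of components.
#' @return matrix of sample scores (`pc1..pc<n_pc>`).
#' @export
helper_pca <- function(g, n_pc = 10) {
  pr <- stats::prcomp(g$dosage, center = TRUE, scale. = FALSE, rank. = n_pc)
  sc <- pr$x
  colnames(sc) <- paste0("pc", seq_len(ncol(sc)))
  sc
}

#' Pipeline run configuration
#'
#' Collects every stage's parameters. Either supply `inputs` (paths to
#' summary statistics, VCFs, phenotype table and gene annotation) or leave
#' it `NULL` to generate a synthetic dataset from `sim`.
#'
#' @param sim a [simulation_config()] (synthetic mode).
#' @param inputs optional named list of input paths: `sumstats`,
#'   `panel_vcf`, `cohort_vcf`, `phenotypes`, `genes`, `gwas` (regional
#'   disease summary statistics for colocalisation; synthetic mode derives
#'   them from the cohort).
#' @param partition a [partition_config()].
#' @param qc named list of QC thresholds passed to [qc_filter_variants()].
#' @param ridge LD-matrix shrinkage for score weights.
#' @param prune_threshold score-correlation exclusion threshold.
#' @param coloc a [coloc_config()].
#' @param fdr FDR level used to select risk-significant scores.
#' @param m_total optional family size for BH adjustment of the risk scan.
#' @param hla_span HLA exclusion span (see [exclude_hla()]); `NULL` disables.
#' @param genomewide_survival test survival/recurrence for every score, not
#'   only the risk-significant set.
#' @param coloc_all_scores colocalise every score in a candidate region,
#'   not only the risk-significant ones.
#' @param outdir output directory for tables and the run manifest; `NULL`
#'   skips writing.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = simulation_config(), inputs = NULL,
                       partition = partition_config(), qc = list(),
                       ridge = 0.01, prune_threshold = 0.90,
                       coloc = coloc_config(), fdr = 0.05, m_total = NULL,
                       hla_span = list(chrom = "6", start = 25e6, end = 35e6),
                       genomewide_survival = FALSE, coloc_all_scores = FALSE,
                       outdir = NULL) {
  if (!is.null(inputs)) {
    missing <- unlist(inputs)[!file.exists(unlist(inputs))]
    if (length(missing))
      stop_input("input path(s) do not exist: ", paste(missing, collapse = ", "))
  }
  structure(list(sim = sim, inputs = inputs, partition = partition, qc = qc,
                 ridge = ridge, prune_threshold = prune_threshold,
                 coloc = coloc, fdr = fdr, m_total = m_total,
                 hla_span = hla_span,
                 genomewide_survival = genomewide_survival,
                 coloc_all_scores = coloc_all_scores, outdir = outdir),
            class = "run_config")
}

# cluster significant score definitions into candidate regions (same
# chromosome, spans closer than min_separation merge)
candidate_regions <- function(defs, min_separation = 1e6) {
  if (!length(defs)) return(list())
  meta <- data.frame(idx = seq_along(defs),
                     chrom = vapply(defs, function(d) as.character(d$chrom), character(1)),
                     start = vapply(defs, function(d) d$start, numeric(1)),
                     end = vapply(defs, function(d) d$end, numeric(1)))
  out <- list()
  for (ch in unique(meta$chrom)) {
    mc <- meta[meta$chrom == ch, , drop = FALSE]
    mc <- mc[order(mc$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(mc$start[-1] - cummax(mc$end)[-nrow(mc)] >= min_separation)))
    for (g in split(mc$idx, grp))
      out[[length(out) + 1L]] <- defs[g]
  }
  out
}

#' Run the full mQTL-score pipeline
#'
#' Executes QC, allele harmonization, HLA exclusion, region partitioning,
#' LD-adjusted score computation, correlation pruning, case-control
#' association with BH FDR control, survival/recurrence models on the
#' risk-significant set, the stage-IV subanalysis, and colocalisation of
#' each risk-significant candidate region against the disease GWAS signal.
#' With no `inputs` in the config, a synthetic dataset (with ground truth)
#' is generated first; re-running with the same config reproduces every
#' output byte-identically.
#'
#' @param config a [run_config()].
#' @param data optional pre-generated dataset (list with `panel`, `mq` as
#'   returned by [simulate_mqtl_sumstats()], and `coh` as returned by
#'   [simulate_cohort()]), bypassing internal simulation.
#' @return object of class `mqtl_pipeline` with elements `risk`, `survival`,
#'   `stage4`, `coloc` (tables), `scores`, `defs`, `regions`, `truth`,
#'   `qc_report`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), data = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$inputs)) {
    if (is.null(data)) {
      panel <- simulate_panel(config$sim)
      mq <- simulate_mqtl_sumstats(panel, config$sim)
      coh <- simulate_cohort(panel, mq$truth, config$sim)
    } else {
      panel <- data$panel; mq <- data$mq; coh <- data$coh
    }
    sumstats <- mq$sumstats
    genes <- mq$genes; probe_genes <- mq$probe_genes
    cohort <- coh$genotypes; phenotypes <- coh$phenotypes
    truth <- coh$truth
    gwas <- NULL
  } else {
    inp <- config$inputs
    sumstats <- read_sumstats(inp$sumstats)
    panel <- read_vcf(inp$panel_vcf)
    cohort <- read_vcf(inp$cohort_vcf)
    phenotypes <- read_phenotypes(inp$phenotypes)
    ann <- read_gene_annotation(inp$genes)
    genes <- ann; probe_genes <- NULL
    truth <- NULL
    gwas <- if (!is.null(inp$gwas)) read_sumstats(inp$gwas) else NULL
  }

  qc <- do.call(qc_filter_variants, c(list(cohort), config$qc))
  cohort <- qc$genotypes
  harm <- harmonize_alleles(sumstats, panel, cohort)
  ss <- exclude_hla(harm$sumstats, config$hla_span)

  regions <- unlist(lapply(split(ss, ss$probe), partition_regions,
                           config = config$partition), recursive = FALSE)
  if (!length(regions)) stop("no trait-associated regions found", call. = FALSE)
  defs <- build_score_definitions(regions, ss, harm$panel, ridge = config$ridge)
  for (k in seq_along(defs))
    if (!is.null(probe_genes))
      defs[[k]]$class_label <- classify_score(defs[[k]], genes, probe_genes)
  scores <- compute_scores(harm$cohort, defs)
  pruned <- prune_correlated_scores(scores, config$prune_threshold)
  scores <- pruned$scores

  risk <- associate_scores(scores, phenotypes, "risk", m_total = config$m_total)
  sig <- risk$score_id[!is.na(risk$fdr_pval) & risk$fdr_pval < config$fdr]
  surv_set <- if (config$genomewide_survival) colnames(scores$values) else sig
  survival_tab <- if (length(surv_set)) {
    sub <- scores; sub$values <- scores$values[, surv_set, drop = FALSE]
    sub$defs <- scores$defs[surv_set]
    do.call(rbind, lapply(c("OS", "CSS", "RFS"), function(oc)
      associate_scores(sub, phenotypes, oc)))
  } else assoc_row("placeholder", "OS")[0, ]
  stage4 <- run_stage4_subanalysis(scores, phenotypes)

  coloc_set <- if (config$coloc_all_scores) names(scores$defs) else sig
  coloc_rows <- list(); coloc_results <- list()
  if (length(coloc_set)) {
    for (cand in candidate_regions(scores$defs[coloc_set],
                                   config$partition$min_separation)) {
      bounds <- define_coloc_region(cand)
      in_reg <- harm$cohort$variants$chrom == bounds$chrom &
        harm$cohort$variants$pos >= bounds$start &
        harm$cohort$variants$pos <= bounds$end
      stats2 <- if (is.null(gwas)) {
        v <- harm$cohort$variants[in_reg, , drop = FALSE]
        fit <- marginal_ols(harm$cohort$dosage[, in_reg, drop = FALSE],
                            phenotypes$status)
        data.frame(snp_id = v$id, pos = v$pos, fit, stringsAsFactors = FALSE)
      } else gwas[gwas$chrom == bounds$chrom & gwas$pos >= bounds$start &
                    gwas$pos <= bounds$end, , drop = FALSE]
      for (def in cand) {
        stats1 <- ss[ss$probe == def$probe_id & ss$snp_id %in% def$snp_ids, ]
        res <- coloc_abf(stats1, stats2, config$coloc, type1 = "quant",
                         type2 = "cc",
                         region_id = sprintf("%s:%d-%d_%s", bounds$chrom,
                                             bounds$start, bounds$end,
                                             def$probe_id))
        coloc_results[[res$region_id]] <- res
        pp <- if (is.null(res$pp)) rep(NA_real_, 5) else unname(res$pp)
        coloc_rows[[length(coloc_rows) + 1L]] <- data.frame(
          region = sprintf("%s:%d-%d", bounds$chrom, bounds$start, bounds$end),
          probe = def$probe_id, n_common = res$n_common,
          pp0 = pp[1], pp1 = pp[2], pp2 = pp[3], pp3 = pp[4], pp4 = pp[5],
          top_snp = res$top_snp, flag = res$flag, stringsAsFactors = FALSE)
      }
    }
  }
  coloc_tab <- if (length(coloc_rows)) do.call(rbind, coloc_rows) else
    data.frame(region = character(0), probe = character(0),
               n_common = integer(0), pp0 = numeric(0), pp1 = numeric(0),
               pp2 = numeric(0), pp3 = numeric(0), pp4 = numeric(0),
               top_snp = character(0), flag = character(0))

  manifest <- list(package = "mqtlscore",
                   version = as.character(utils::packageVersion("mqtlscore")),
                   seed = config$sim$seed,
                   n_scores = ncol(scores$values),
                   n_pruned = nrow(pruned$dropped),
                   n_risk_significant = length(sig),
                   fdr = config$fdr)
  out <- structure(list(risk = risk, survival = survival_tab, stage4 = stage4,
                        coloc = coloc_tab, coloc_results = coloc_results,
                        scores = scores, defs = scores$defs, regions = regions,
                        truth = truth, qc_report = qc$report,
                        manifest = manifest, config = config),
                   class = "mqtl_pipeline")
  if (!is.null(config$outdir)) write_pipeline_outputs(out, config$outdir)
  out
}

write_pipeline_outputs <- function(x, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(outdir, "config.yaml")
  cfg <- x$config
  cfg$sim <- unclass(cfg$sim); cfg$partition <- unclass(cfg$partition)
  cfg$coloc <- unclass(cfg$coloc)
  cfg$outdir <- NULL   # hash covers the analysis config, not where it lands
  yaml::write_yaml(unclass(cfg), cfg_path)
  hash <- unname(tools::md5sum(cfg_path))
  tab <- function(df, name) {
    p <- file.path(outdir, name)
    con <- file(p, "w")
    writeLines(paste0("# config_hash: ", hash), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  tab(x$risk, "risk_associations.tsv")
  tab(x$survival, "survival_associations.tsv")
  tab(x$stage4, "stage4_associations.tsv")
  tab(x$coloc, "colocalisation.tsv")
  tab(regions_table(x$regions), "regions.tsv")
  man <- c(x$manifest, config_hash = hash)
  yaml::write_yaml(man, file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}

#' @export
print.mqtl_pipeline <- function(x, ...) {
  cat("mQTL-score pipeline run\n")
  cat(sprintf("  scores tested: %d (%d dropped by pruning)\n",
              x$manifest$n_scores, x$manifest$n_pruned))
  cat(sprintf("  risk-significant at FDR %.2f: %d\n",
              x$manifest$fdr, x$manifest$n_risk_significant))
  cat(sprintf("  survival/recurrence rows: %d; colocalised regions: %d\n",
              nrow(x$survival), sum(x$coloc$pp4 > x$config$coloc$pph4_call,
                                    na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.mqtl_pipeline <- function(object, ...) {
  print(object)
  sig <- object$risk[!is.na(object$risk$fdr_pval) &
                       object$risk$fdr_pval < object$config$fdr, ]
  if (nrow(sig)) {
    cat("\nrisk-significant scores:\n")
    print(sig[order(sig$pval), c("score_id", "estimate", "se", "pval", "fdr_pval")],
          row.names = FALSE)
  }
  invisible(object)
}
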