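#' Colocalisation configuration
#'
#' Priors and decision rules of the five-hypothesis approximate-Bayes-factor
#' colocalisation test: per-SNP prior probabilities of causality for each
#' trait (`p1`, `p2`) and for both (`p12`), prior effect-size scales for
#' quantitative and case-control traits, the minimum shared-variant count,
#' and the posterior threshold at which a region is called colocalised.
#'
#' @param p1,p2 per-SNP causal prior for trait 1 / trait 2 (default 1e-4).
#' @param p12 per-SNP shared-causal prior (default 1e-5; must not exceed
#'   `min(p1, p2)`).
#' @param prior_sd_quant prior effect SD for a quantitative trait (0.15).
#' @param prior_sd_cc prior SD on the log-odds scale for a case-control
#'   trait (0.2).
#' @param min_overlap minimum variants shared between the two traits (10).
#' @param pph4_call posterior-probability threshold for declaring a shared
#'   causal variant (0.80).
#' @return object of class `coloc_config`.
#' @export
coloc_config <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         prior_sd_quant = 0.15, prior_sd_cc = 0.2,
                         min_overlap = 10, pph4_call = 0.80) {
  if (any(c(p1, p2, p12) <= 0)) stop_input("priors must be positive")
  if (p12 > min(p1, p2)) stop_input("p12 must not exceed min(p1, p2)")
  if (min_overlap < 1) stop_input("min_overlap must be at least 1")
  structure(list(p1 = p1, p2 = p2, p12 = p12,
                 prior_sd_quant = prior_sd_quant, prior_sd_cc = prior_sd_cc,
                 min_overlap = min_overlap, pph4_call = pph4_call),
            class = "coloc_config")
}

#' Wakefield log approximate Bayes factor for one SNP
#'
#' With `z = beta/se` and shrinkage `r = prior_sd^2 / (prior_sd^2 + se^2)`,
#' returns `0.5 * (log(1 - r) + r * z^2)` — the log ratio of the marginal
#' likelihood of the data under a normal effect prior to that under the
#' point null. Vectorised over `beta`/`se`.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), positive.
#' @param prior_sd prior effect-size scale, positive.
#' @return log Bayes factor(s).
#' @export
snp_log_abf <- function(beta, se, prior_sd) {
  if (any(!is.finite(beta)) || any(!is.finite(se)) || !is.finite(prior_sd))
    stop_input("non-finite inputs to snp_log_abf")
  if (any(se <= 0) || prior_sd < 0) stop_input("se and prior_sd must be positive")
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  z <- beta / se
  0.5 * (log1p(-r) + r * z^2)
}

# log(S1*S2 - S12) from the three log sums, guarded against cancellation
log_h3_term <- function(lS1, lS2, lS12) {
  d <- lS12 - (lS1 + lS2)
  if (d >= 0) return(-Inf)          # cross term exhausted (e.g. single SNP)
  lS1 + lS2 + log1p(-exp(d))
}

#' Approximate-Bayes-factor colocalisation of two regional signals
#'
#' Under the assumption of at most one causal variant per trait in the
#' region, combines per-SNP Wakefield ABFs into posterior probabilities of
#' the five hypotheses — H0 neither trait associated, H1/H2 one trait only,
#' H3 both traits with distinct causal variants, H4 one shared causal
#' variant. Likelihood sums `S1 = sum_j ABF1_j`, `S2 = sum_j ABF2_j`,
#' `S12 = sum_j ABF1_j ABF2_j` and the H3 cross term `S1 S2 - S12` are
#' weighted by the priors (1, p1 S1, p2 S2, p1 p2 (S1 S2 - S12), p12 S12)
#' and normalised, all in log space. Variants are matched by `snp_id`;
#' regions sharing fewer than `min_overlap` variants are flagged and return
#' no probabilities.
#'
#' @param stats1,stats2 regional summary statistics (columns `snp_id, beta,
#'   se`; allele-harmonized).
#' @param config a [coloc_config()].
#' @param type1,type2 `"quant"` or `"cc"`, selecting the per-trait prior
#'   effect scale.
#' @param region_id label carried into the result.
#' @return object of class `coloc_result` with fields `region_id`,
#'   `n_common`, `pp` (named numeric, H0..H4), `top_snp`, `per_snp_h4`,
#'   `flag`, `stats` (merged per-SNP table).
#' @export
coloc_abf <- function(stats1, stats2, config = coloc_config(),
                      type1 = "quant", type2 = "cc", region_id = "region") {
  common <- intersect(stats1$snp_id, stats2$snp_id)
  n_common <- length(common)
  if (n_common < config$min_overlap)
    return(structure(list(region_id = region_id, n_common = n_common,
                          pp = NULL, top_snp = NA_character_,
                          per_snp_h4 = NULL,
                          flag = "Not enough common SNPs found", stats = NULL),
                     class = "coloc_result"))
  s1 <- stats1[match(common, stats1$snp_id), , drop = FALSE]
  s2 <- stats2[match(common, stats2$snp_id), , drop = FALSE]
  sd1 <- if (type1 == "cc") config$prior_sd_cc else config$prior_sd_quant
  sd2 <- if (type2 == "cc") config$prior_sd_cc else config$prior_sd_quant
  l1 <- snp_log_abf(s1$beta, s1$se, sd1)
  l2 <- snp_log_abf(s2$beta, s2$se, sd2)
  lS1 <- logsumexp(l1)
  lS2 <- logsumexp(l2)
  lS12 <- logsumexp(l1 + l2)
  lpost <- c(H0 = 0,
             H1 = log(config$p1) + lS1,
             H2 = log(config$p2) + lS2,
             H3 = log(config$p1) + log(config$p2) + log_h3_term(lS1, lS2, lS12),
             H4 = log(config$p12) + lS12)
  pp <- exp(lpost - logsumexp(lpost))
  per_snp_h4 <- exp(l1 + l2 - lS12)
  names(per_snp_h4) <- common
  top <- if (which.max(pp) == 5L || pp["H4"] > config$pph4_call)
    common[which.max(per_snp_h4)] else NA_character_
  merged <- data.frame(snp_id = common,
                       pos = if (!is.null(s1$pos)) s1$pos else NA_integer_,
                       beta1 = s1$beta, se1 = s1$se,
                       pval1 = if (!is.null(s1$pval)) s1$pval else NA_real_,
                       beta2 = s2$beta, se2 = s2$se,
                       pval2 = if (!is.null(s2$pval)) s2$pval else NA_real_,
                       h4_weight = per_snp_h4, stringsAsFactors = FALSE)
  structure(list(region_id = region_id, n_common = n_common, pp = pp,
                 top_snp = top, per_snp_h4 = per_snp_h4, flag = "",
                 stats = merged),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("colocalisation:", x$region_id, "-", x$n_common, "shared variants\n")
  if (nzchar(x$flag)) {
    cat(" ", x$flag, "\n")
  } else {
    cat("  PP:", paste(sprintf("%s=%.3f", names(x$pp), x$pp), collapse = " "), "\n")
    if (!is.na(x$top_snp)) cat("  top colocalised SNP:", x$top_snp, "\n")
  }
  invisible(x)
}

#' Regional association plot for a colocalisation result
#'
#' Two stacked panels of -log10 p-values (trait 1 above, trait 2 below)
#' across the shared variants, with the top colocalised SNP highlighted.
#'
#' @param x a [coloc_abf()] result with probabilities.
#' @param ... passed to [graphics::plot()].
#' @export
plot.coloc_result <- function(x, ...) {
  if (is.null(x$stats)) stop_input("nothing to plot: ", x$flag)
  s <- x$stats
  p1 <- if (all(is.na(s$pval1))) 2 * stats::pnorm(-abs(s$beta1 / s$se1)) else s$pval1
  p2 <- if (all(is.na(s$pval2))) 2 * stats::pnorm(-abs(s$beta2 / s$se2)) else s$pval2
  xv <- if (all(is.na(s$pos))) seq_len(nrow(s)) else s$pos
  old <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 2, 1))
  on.exit(graphics::par(old))
  hl <- s$snp_id == x$top_snp
  graphics::plot(xv, -log10(p1), pch = 19, col = ifelse(hl, "red", "grey40"),
                 xlab = "", ylab = expression(-log[10](p)),
                 main = paste(x$region_id, "- trait 1"), ...)
  graphics::plot(xv, -log10(p2), pch = 19, col = ifelse(hl, "red", "grey40"),
                 xlab = "position", ylab = expression(-log[10](p)),
                 main = "trait 2", ...)
  invisible(x)
}

#' Candidate-region bounds for colocalisation
#'
#' The region spans all SNPs of all supplied score definitions:
#' `[min, max]` over member positions. Definitions on more than one
#' chromosome are an error (trans components are analysed separately in
#' their own coordinates).
#'
#' @param defs list of score definitions.
#' @return list with `chrom`, `start`, `end`.
#' @export
define_coloc_region <- function(defs) {
  if (!length(defs)) stop_input("at least one score definition is required")
  chroms <- unique(vapply(defs, function(d) as.character(d$chrom), character(1)))
  if (length(chroms) > 1)
    stop_input("definitions span multiple chromosomes: ",
               paste(chroms, collapse = ", "))
  list(chrom = chroms,
       start = min(vapply(defs, function(d) d$start, numeric(1))),
       end = max(vapply(defs, function(d) d$end, numeric(1))))
}
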