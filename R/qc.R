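#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on genotype counts: given the observed allele
#' counts, the probability of each possible heterozygote count is computed
#' under the standard hypergeometric-type HWE distribution, and the p-value
#' is the total probability of configurations no more probable than the
#' observed one.
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts, not all zero.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0)) stop_input("genotype counts must be non-negative")
  if (sum(counts) == 0) stop_input("genotype counts must not all be zero")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)
  # P(h) proportional to 2^h / ((nA-h)/2)! h! ((na-h)/2)!  given allele counts
  lp <- hets * log(2) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((na - hets) / 2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[hets == n_Aa]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

#' QC report container
#' @param removed named integer vector of variants removed per rule.
#' @param thresholds named list echoing the thresholds applied.
#' @param n_in,n_out variant counts before and after filtering.
#' @return object of class `qc_report`.
#' @export
qc_report <- function(removed, thresholds, n_in, n_out) {
  stopifnot(n_in - n_out == sum(removed))
  structure(list(removed = removed, thresholds = thresholds,
                 n_in = n_in, n_out = n_out), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("variant QC: %d in, %d retained\n", x$n_in, x$n_out))
  for (rule in names(x$removed))
    cat(sprintf("  %-10s removed %4d  (threshold %s)\n", rule, x$removed[[rule]],
                format(x$thresholds[[rule]])))
  invisible(x)
}

#' Variant-level quality control
#'
#' Applies, in order, call-rate, minor-allele-frequency, Hardy-Weinberg and
#' imputation-info filters; each variant is charged to the first rule it
#' fails. MAF is computed from mean dosage; the HWE exact test runs on hard
#' calls obtained by rounding dosages. The default MAF threshold is 0.05%
#' (0.0005).
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency.
#' @param hwe_p_min minimum exact-test HWE p-value.
#' @param info_min minimum imputation info score (applied only where an
#'   `info` column is present).
#' @param callrate_min minimum per-variant call rate.
#' @return list with the filtered `genotypes` and a [qc_report()].
#' @export
qc_filter_variants <- function(g, maf_min = 0.0005, hwe_p_min = 1e-5,
                               info_min = 0.8, callrate_min = 0.95) {
  stopifnot(inherits(g, "genotype_matrix"))
  thr <- c(callrate = callrate_min, maf = maf_min, hwe = hwe_p_min, info = info_min)
  if (any(thr < 0 | thr > 1)) stop_input("QC thresholds must lie in [0,1]")
  d <- g$dosage
  m <- ncol(d)
  callrate <- colMeans(!is.na(d))
  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hard <- round(d)
  hwe_p <- vapply(seq_len(m), function(j) {
    h <- hard[!is.na(hard[, j]), j]
    cnt <- c(sum(h == 0), sum(h == 1), sum(h == 2))
    if (sum(cnt) == 0) return(1)
    hwe_exact_test(cnt[1], cnt[2], cnt[3])
  }, numeric(1))
  info <- if (!is.null(g$variants$info)) g$variants$info else rep(NA_real_, m)

  fail_call <- callrate < callrate_min
  fail_maf <- !fail_call & maf < maf_min
  fail_hwe <- !fail_call & !fail_maf & hwe_p < hwe_p_min
  fail_info <- !fail_call & !fail_maf & !fail_hwe & !is.na(info) & info < info_min
  keep <- !(fail_call | fail_maf | fail_hwe | fail_info)
  if (!any(keep)) warning("no variants retained after QC filtering")
  out <- g
  out$dosage <- g$dosage[, keep, drop = FALSE]
  out$variants <- g$variants[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  rep <- qc_report(c(callrate = sum(fail_call), maf = sum(fail_maf),
                     hwe = sum(fail_hwe), info = sum(fail_info)),
                   as.list(thr), m, sum(keep))
  list(genotypes = out, report = rep)
}

#' Resolve first-degree relative pairs
#'
#' For each related pair, excludes the control if exactly one member is a
#' control; if both members are cases (or both controls), excludes the one
#' with the lower call rate; equal call rates break ties by excluding the
#' lexicographically later sample id. At most one member of any pair is
#' excluded.
#'
#' @param pairs data.frame with columns `id1`, `id2`.
#' @param status named vector (1 = case, 0 = control) covering all paired ids.
#' @param callrate named numeric vector of per-sample call rates.
#' @return character vector of sample ids to exclude.
#' @export
resolve_relatedness <- function(pairs, status, callrate) {
  ids <- unique(c(pairs$id1, pairs$id2))
  unknown <- setdiff(ids, intersect(names(status), names(callrate)))
  if (length(unknown))
    stop_input("pair references unknown sample(s): ", paste(unknown, collapse = ", "))
  excl <- character(0)
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$id1[k]; b <- pairs$id2[k]
    drop <- if (status[a] != status[b]) {
      if (status[a] == 0) a else b
    } else if (callrate[a] != callrate[b]) {
      if (callrate[a] < callrate[b]) a else b
    } else {
      max(a, b)
    }
    excl <- union(excl, drop)
  }
  excl
}

is_palindromic <- function(a1, a2) {
  p <- paste(pmin(a1, a2), pmax(a1, a2))
  p %in% c("A T", "C G")
}

#' Harmonize alleles across summary statistics, panel and cohort
#'
#' Matches variants by (chrom, 1-based pos) across all three inputs. Where
#' the summary-statistic effect allele equals the VCF alternate allele the
#' beta is kept; where effect and other alleles are swapped relative to
#' ref/alt the beta is negated so that it always refers to the alternate
#' allele counted by the dosage. Strand-ambiguous (A/T, C/G) variants are
#' removed, as are variants whose alleles cannot be reconciled or that are
#' absent from any input. Cohort variants whose ref/alt coding is swapped
#' relative to the panel have their dosages flipped to `2 - d`.
#'
#' @param sumstats summary-statistic data.frame ([read_sumstats()] layout).
#' @param panel,cohort [genotype_matrix()] objects.
#' @return list with aligned `sumstats`, `panel`, `cohort` and a `report`
#'   data.frame of per-rule drop counts.
#' @export
harmonize_alleles <- function(sumstats, panel, cohort) {
  key <- function(chrom, pos) paste(chrom, pos, sep = ":")
  ss_key <- key(sumstats$chrom, sumstats$pos)
  pv <- panel$variants; cv <- cohort$variants
  p_key <- key(pv$chrom, pv$pos); c_key <- key(cv$chrom, cv$pos)

  n0 <- nrow(sumstats)
  palin <- is_palindromic(sumstats$effect_allele, sumstats$other_allele)
  shared <- ss_key %in% p_key & ss_key %in% c_key
  keep <- shared & !palin
  ss <- sumstats[keep, , drop = FALSE]
  pi <- match(key(ss$chrom, ss$pos), p_key)
  same <- ss$effect_allele == pv$alt[pi] & ss$other_allele == pv$ref[pi]
  swap <- ss$effect_allele == pv$ref[pi] & ss$other_allele == pv$alt[pi]
  mismatch <- !(same | swap)
  ss <- ss[!mismatch, , drop = FALSE]
  ss$beta[swap[!mismatch]] <- -ss$beta[swap[!mismatch]]
  if (!nrow(ss)) stop_input("no overlapping variants after harmonization")

  pi <- match(key(ss$chrom, ss$pos), p_key)
  ci <- match(key(ss$chrom, ss$pos), c_key)
  # align cohort coding to the panel's ref/alt
  cflip <- cv$ref[ci] == pv$alt[pi] & cv$alt[ci] == pv$ref[pi]
  cmis <- !cflip & !(cv$ref[ci] == pv$ref[pi] & cv$alt[ci] == pv$alt[pi])
  ss <- ss[!cmis, , drop = FALSE]
  pi <- pi[!cmis]; ci <- ci[!cmis]; cflip <- cflip[!cmis]

  sub_geno <- function(g, idx, flip = NULL, new_meta = NULL) {
    d <- g$dosage[, idx, drop = FALSE]
    if (!is.null(flip) && any(flip)) d[, flip] <- 2 - d[, flip]
    v <- if (is.null(new_meta)) g$variants[idx, , drop = FALSE] else new_meta
    rownames(v) <- NULL
    out <- g
    out$dosage <- d
    colnames(out$dosage) <- v$id
    out$variants <- v
    out
  }
  pv_sub <- pv[pi, , drop = FALSE]
  cv_sub <- cv[ci, , drop = FALSE]
  cv_sub[c("id", "ref", "alt")] <- pv_sub[c("id", "ref", "alt")]
  ss$snp_id <- pv_sub$id
  report <- data.frame(rule = c("palindromic", "unmatched", "allele_mismatch"),
                       dropped = c(sum(palin & shared), sum(!shared),
                                   sum(mismatch) + sum(cmis)))
  list(sumstats = ss,
       panel = sub_geno(panel, pi),
       cohort = sub_geno(cohort, ci, flip = cflip, new_meta = cv_sub),
       report = report)
}
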