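#' SNP-SNP correlation matrix from a reference panel
#'
#' Pearson correlation of dosages across panel samples, optionally shrunk
#' towards the identity as `R_reg = (1 - ridge) R + ridge I`, which keeps a
#' unit diagonal while restoring invertibility for rank-deficient regions.
#'
#' @param panel a [genotype_matrix()].
#' @param snp_ids variant ids to include (order preserved).
#' @param ridge shrinkage weight in \[0,1); 0 leaves the raw correlation.
#' @return object of class `ld_matrix` with fields `snp_ids`, `R`, `ridge`.
#' @export
compute_ld_matrix <- function(panel, snp_ids, ridge = 0.01) {
  stopifnot(inherits(panel, "genotype_matrix"))
  if (nrow(panel$dosage) < 2) stop_input("panel must contain at least 2 samples")
  missing <- setdiff(snp_ids, panel$variants$id)
  if (length(missing))
    stop_input("SNPs absent from panel: ", paste(missing, collapse = ", "))
  d <- panel$dosage[, snp_ids, drop = FALSE]
  sds <- apply(d, 2, stats::sd)
  if (any(sds == 0))
    stop_input("zero-variance SNP(s) in panel: ",
               paste(snp_ids[sds == 0], collapse = ", "))
  R <- stats::cor(d)
  if (ridge > 0) R <- (1 - ridge) * R + ridge * diag(ncol(R))
  structure(list(snp_ids = snp_ids, R = R, ridge = ridge), class = "ld_matrix")
}

#' Solve for LD-adjusted score weights
#'
#' Returns `w` solving `R w = beta` by a numerically stable solve (no
#' explicit inversion), so that the genotypic score `g' w = g' R^{-1} beta`
#' corrects each marginal mQTL effect estimate for the LD among the region's
#' SNPs.
#'
#' @param betas marginal effect estimates, ordered as `R$snp_ids`.
#' @param R an [compute_ld_matrix()] result (or plain correlation matrix).
#' @param tol maximum allowed residual `max|R w - beta|`.
#' @return numeric weight vector.
#' @export
compute_score_weights <- function(betas, R, tol = 1e-8) {
  Rm <- if (inherits(R, "ld_matrix")) R$R else R
  if (length(betas) != nrow(Rm)) stop_input("beta and R dimensions disagree")
  w <- tryCatch(solve(Rm, betas), error = function(e)
    stop_input("LD matrix is singular; increase the ridge parameter or prune SNPs"))
  if (max(abs(Rm %*% w - betas)) > tol * max(1, max(abs(betas))))
    stop_input("ill-conditioned LD solve; increase the ridge parameter or prune SNPs")
  as.numeric(w)
}

#' Assemble score definitions for a set of regions
#'
#' For each trait-associated region, gathers the member SNPs' marginal
#' betas, computes the panel LD matrix and the LD-adjusted weight vector.
#'
#' @param regions list from [partition_regions()] (possibly over several
#'   probes).
#' @param sumstats harmonized summary statistics.
#' @param panel harmonized reference panel.
#' @param ridge LD-matrix shrinkage (see [compute_ld_matrix()]).
#' @return list of score definitions: `score_id, probe_id, chrom, start,
#'   end, snp_ids, betas, weights, ld, ld_matrix_hash, min_pval,
#'   class_label`.
#' @export
build_score_definitions <- function(regions, sumstats, panel, ridge = 0.01) {
  defs <- vector("list", length(regions))
  for (k in seq_along(regions)) {
    r <- regions[[k]]
    ids <- intersect(r$snp_ids, panel$variants$id)
    if (!length(ids)) next
    ss <- sumstats[match(ids, sumstats$snp_id), , drop = FALSE]
    ld <- compute_ld_matrix(panel, ids, ridge = ridge)
    w <- compute_score_weights(ss$beta, ld)
    defs[[k]] <- list(score_id = sprintf("%s_%s_%d", r$probe_id, r$chrom, r$start),
                      probe_id = r$probe_id, chrom = r$chrom,
                      start = r$start, end = r$end,
                      snp_ids = ids, betas = ss$beta, weights = w, ld = ld,
                      ld_matrix_hash = fingerprint(ld$R),
                      min_pval = r$min_pval, class_label = "unclassified")
  }
  defs[!vapply(defs, is.null, logical(1))]
}

#' Compute genotypic scores for a cohort
#'
#' Score of sample `i` for definition `t` is the dot product of the sample's
#' dosages with the definition's LD-adjusted weights. Definition SNPs absent
#' from the cohort are dropped and the weights re-solved on the re-subset LD
#' matrix; a definition with no usable SNPs is dropped with a warning.
#'
#' @param cohort a [genotype_matrix()].
#' @param defs list from [build_score_definitions()].
#' @return object of class `score_matrix`: fields `values` (samples x
#'   scores), `defs`.
#' @export
compute_scores <- function(cohort, defs) {
  stopifnot(inherits(cohort, "genotype_matrix"))
  cols <- list(); kept <- list()
  for (def in defs) {
    have <- def$snp_ids %in% cohort$variants$id
    if (!any(have)) {
      warning("score ", def$score_id, " dropped: no usable SNPs in cohort")
      next
    }
    if (!all(have)) {
      keep <- which(have)
      def$snp_ids <- def$snp_ids[keep]
      def$betas <- def$betas[keep]
      def$ld$R <- def$ld$R[keep, keep, drop = FALSE]
      def$ld$snp_ids <- def$snp_ids
      def$weights <- compute_score_weights(def$betas, def$ld)
      def$ld_matrix_hash <- fingerprint(def$ld$R)
    }
    cols[[def$score_id]] <- drop(cohort$dosage[, def$snp_ids, drop = FALSE] %*% def$weights)
    kept[[def$score_id]] <- def
  }
  if (!length(cols)) stop_input("no scores could be computed")
  values <- do.call(cbind, cols)
  rownames(values) <- cohort$sample_ids
  structure(list(values = values, defs = kept), class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d samples x %d scores\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Classify a score by distance to its tagged gene
#'
#' Distance is 0 when the score's region overlaps the gene's transcription
#' span, else the minimal gap between region and span. Scores on a different
#' chromosome from the gene are `trans`; otherwise a distance under 50 kb is
#' `cis`, between 50 kb and 5 Mb inclusive `cis-x`, and beyond 5 Mb `trans`.
#' A probe without a mapped gene yields `"unclassified"` (the score is
#' retained).
#'
#' @param def one score definition.
#' @param genes gene annotation data.frame (`gene, chrom, start, end`).
#' @param probe_genes probe-to-gene map (`probe, gene`).
#' @return one of `"cis", "cis-x", "trans", "unclassified"`.
#' @export
classify_score <- function(def, genes, probe_genes) {
  gn <- probe_genes$gene[probe_genes$probe == def$probe_id]
  gn <- intersect(gn, genes$gene)
  if (!length(gn)) return("unclassified")
  labs <- vapply(gn, function(g) {
    gi <- genes[genes$gene == g, ][1, ]
    if (as.character(gi$chrom) != as.character(def$chrom)) return("trans")
    gap <- max(0, max(gi$start, def$start) - min(gi$end, def$end))
    if (gap < 50e3) "cis" else if (gap <= 5e6) "cis-x" else "trans"
  }, character(1))
  # closest relationship wins when a probe maps to several genes
  for (lab in c("cis", "cis-x", "trans")) if (lab %in% labs) return(lab)
  "unclassified"
}

#' Greedy pruning of highly correlated scores
#'
#' Scores are visited in order of their region's smallest member p-value
#' (most significant first); a score is kept iff its absolute Pearson
#' correlation with every already-kept score does not exceed `threshold`.
#' Constant score columns correlate with nothing, are kept, and flagged.
#'
#' @param scores a [compute_scores()] result.
#' @param threshold correlation cut-off (default 0.90).
#' @return list with the pruned `scores` and a `dropped` data.frame mapping
#'   each dropped score to the kept score that displaced it.
#' @export
prune_correlated_scores <- function(scores, threshold = 0.90) {
  stopifnot(inherits(scores, "score_matrix"))
  ids <- colnames(scores$values)
  if (!length(ids)) stop_input("score matrix has no columns")
  minp <- vapply(scores$defs[ids], function(d) d$min_pval, numeric(1))
  ord <- ids[order(minp)]
  sds <- apply(scores$values, 2, stats::sd)
  constant <- names(sds)[sds == 0]
  if (length(constant))
    warning("constant score column(s) kept but non-informative: ",
            paste(constant, collapse = ", "))
  kept <- character(0)
  dropped <- data.frame(score_id = character(0), displaced_by = character(0))
  for (id in ord) {
    if (sds[id] == 0) { kept <- c(kept, id); next }
    live <- kept[sds[kept] > 0]
    if (length(live)) {
      r <- abs(stats::cor(scores$values[, id], scores$values[, live, drop = FALSE]))
      if (any(r > threshold)) {
        dropped <- rbind(dropped, data.frame(score_id = id,
                                             displaced_by = live[which.max(r)]))
        next
      }
    }
    kept <- c(kept, id)
  }
  kept <- ids[ids %in% kept]   # restore original column order
  out <- scores
  out$values <- scores$values[, kept, drop = FALSE]
  out$defs <- scores$defs[kept]
  list(scores = out, dropped = dropped)
}

#' Exclude the HLA region from summary statistics
#'
#' Removes SNPs inside the given span (default chr6:25,000,000-35,000,000)
#' before region partitioning, avoiding scores built on the exceptionally
#' strong LD of the MHC.
#'
#' @param sumstats summary-statistic data.frame.
#' @param hla_span list with `chrom`, `start`, `end`; `NULL` disables.
#' @return filtered data.frame.
#' @export
exclude_hla <- function(sumstats,
                        hla_span = list(chrom = "6", start = 25e6, end = 35e6)) {
  if (is.null(hla_span)) return(sumstats)
  inside <- sumstats$chrom == as.character(hla_span$chrom) &
    sumstats$pos >= hla_span$start & sumstats$pos <= hla_span$end
  sumstats[!inside, , drop = FALSE]
}

#' Serialize score definitions
#'
#' Writes the tab-delimited weights layout
#' `score_id probe chrom pos effect_allele weight`.
#' @param defs list from [build_score_definitions()].
#' @param sumstats harmonized summary statistics (source of effect alleles).
#' @param path output path.
#' @export
write_score_definitions <- function(defs, sumstats, path) {
  rows <- lapply(defs, function(d) {
    ss <- sumstats[match(d$snp_ids, sumstats$snp_id), ]
    data.frame(score_id = d$score_id, probe = d$probe_id, chrom = d$chrom,
               pos = ss$pos, effect_allele = ss$effect_allele,
               weight = d$weights, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
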