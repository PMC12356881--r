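#' Model specification for association testing
#'
#' Names the adjustment covariates and, for survival models, the
#' stratification variable.
#'
#' @param covariates covariate column names in the phenotype table.
#' @param strata stratification variable for survival/recurrence models.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(covariates = c("age", "sex", paste0("pc", 1:10)),
                       strata = "stage") {
  structure(list(covariates = covariates, strata = strata), class = "model_spec")
}

assoc_row <- function(score_id, outcome, estimate = NA_real_, se = NA_real_,
                      pval = NA_real_, n_used = NA_integer_,
                      events_used = NA_integer_, flag = "") {
  data.frame(score_id = score_id, outcome = outcome, estimate = estimate,
             se = se, pval = pval, fdr_pval = NA_real_, n_used = n_used,
             events_used = events_used, flag = flag, stringsAsFactors = FALSE)
}

#' Logistic case-control association of one score
#'
#' Maximum-likelihood logistic fit of case status on the score plus the
#' adjustment covariates, on complete cases. Returns the Wald estimate
#' (log-odds per unit score), its SE and two-sided p-value. Degenerate
#' inputs (constant score, one outcome class, separation, non-convergence)
#' come back as flagged rows, never exceptions.
#'
#' @param score named numeric vector of score values (names = sample ids) or
#'   unnamed vector aligned with `phenotypes` rows.
#' @param phenotypes phenotype table.
#' @param spec a [model_spec()].
#' @param score_id label for the output row.
#' @param outcome_col binary outcome column (default `"status"`).
#' @param outcome_label outcome name in the result.
#' @param subset optional logical vector restricting the rows used.
#' @return one-row data.frame (`score_id, outcome, estimate, se, pval,
#'   fdr_pval, n_used, events_used, flag`).
#' @export
fit_risk_model <- function(score, phenotypes, spec = model_spec(),
                           score_id = "score", outcome_col = "status",
                           outcome_label = "risk", subset = NULL) {
  df <- data.frame(.y = phenotypes[[outcome_col]], .score = as.numeric(score),
                   phenotypes[spec$covariates])
  if (!is.null(subset)) df <- df[which(subset), , drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n == 0 || length(unique(df$.y)) < 2)
    return(assoc_row(score_id, outcome_label, n_used = n, flag = "degenerate_outcome"))
  if (stats::sd(df$.score) == 0)
    return(assoc_row(score_id, outcome_label, n_used = n, flag = "constant_score"))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  if (!".score" %in% rownames(co) || !fit$converged)
    return(assoc_row(score_id, outcome_label, n_used = n, flag = "no_convergence"))
  flag <- if (sep || abs(co[".score", 1]) > 15) "possible_separation" else ""
  assoc_row(score_id, outcome_label, co[".score", 1], co[".score", 2],
            co[".score", 4], n, sum(df$.y), flag)
}

#' Cox proportional-hazards association of one score
#'
#' Stratified partial-likelihood fit (Efron tie handling) of the requested
#' outcome on the score plus adjustment covariates, restricted to cases with
#' non-missing stage and follow-up. Event/censor encodings: `OS` uses death
#' from any cause; `CSS` treats non-disease deaths as censored; `RFS` uses
#' recurrence, with non-recurrent patients censored at death or end of
#' follow-up. The estimate is the log hazard ratio per unit score.
#'
#' @inheritParams fit_risk_model
#' @param outcome one of `"OS"`, `"CSS"`, `"RFS"`.
#' @return one-row data.frame as in [fit_risk_model()].
#' @export
fit_survival_model <- function(score, phenotypes, spec = model_spec(),
                               outcome = c("OS", "CSS", "RFS"),
                               score_id = "score") {
  outcome <- match.arg(outcome)
  time <- switch(outcome, OS = phenotypes$os_time, CSS = phenotypes$os_time,
                 RFS = phenotypes$rfs_time)
  event <- switch(outcome, OS = phenotypes$os_event,
                  CSS = phenotypes$css_event, RFS = phenotypes$rfs_event)
  df <- data.frame(.time = time, .event = event, .score = as.numeric(score),
                   .stage = phenotypes[[spec$strata]], phenotypes[spec$covariates])
  df <- df[phenotypes$status == 1 & stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df); ev <- sum(df$.event)
  if (n == 0 || ev == 0)
    return(assoc_row(score_id, outcome, n_used = n, events_used = ev,
                     flag = "no_events"))
  if (stats::sd(df$.score) == 0)
    return(assoc_row(score_id, outcome, n_used = n, events_used = ev,
                     flag = "constant_score"))
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~ .score +",
    paste(spec$covariates, collapse = " + "), "+ survival::strata(.stage)"))
  fit <- tryCatch(survival::coxph(fml, data = df, ties = "efron"),
                  error = function(e) NULL,
                  warning = function(w) suppressWarnings(
                    survival::coxph(fml, data = df, ties = "efron")))
  if (is.null(fit))
    return(assoc_row(score_id, outcome, n_used = n, events_used = ev,
                     flag = "no_convergence"))
  co <- summary(fit)$coefficients
  assoc_row(score_id, outcome, co[".score", "coef"], co[".score", "se(coef)"],
            co[".score", "Pr(>|z|)"], n, ev)
}

#' Stage-IV-at-presentation subanalysis
#'
#' Cases only: logistic model of stage IV versus all other stages on each
#' score, with the usual adjustment covariates, asking whether any
#' methylation signal marks advanced disease at presentation.
#'
#' @param scores a [compute_scores()] result (or plain matrix, samples in
#'   rows).
#' @param phenotypes phenotype table.
#' @param spec a [model_spec()].
#' @return data.frame of association rows (outcome `"risk_stage4"`) with a
#'   BH-adjusted `fdr_pval` column.
#' @export
run_stage4_subanalysis <- function(scores, phenotypes, spec = model_spec()) {
  vals <- if (inherits(scores, "score_matrix")) scores$values else as.matrix(scores)
  cases <- phenotypes$status == 1 & !is.na(phenotypes$stage)
  stages <- unique(phenotypes$stage[cases])
  if (length(stages) < 2)
    stop_input("stage-IV subanalysis needs at least two stage categories among cases")
  ph <- phenotypes
  ph$.stage4 <- as.integer(phenotypes$stage == "IV")
  res <- do.call(rbind, lapply(colnames(vals), function(id)
    fit_risk_model(vals[, id], ph, spec, score_id = id,
                   outcome_col = ".stage4", outcome_label = "risk_stage4",
                   subset = cases)))
  ok <- !is.na(res$pval)
  res$fdr_pval[ok] <- bh_adjust(res$pval[ok])
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts the p-values ascending, forms `p_(j) * m_total / j`, enforces
#' monotonicity by taking the running minimum from the largest rank down,
#' caps at 1, and maps back to input order. `m_total` may exceed the number
#' of supplied p-values, supporting adjustment of the top fraction of a
#' larger family from printed values alone.
#'
#' @param pvals raw p-values in (0,1].
#' @param m_total size of the test family (default `length(pvals)`).
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals, m_total = length(pvals)) {
  k <- length(pvals)
  if (m_total < k) stop_input("m_total must be at least length(pvals)")
  if (k == 0) return(numeric(0))
  if (any(pvals <= 0 | pvals > 1)) stop_input("p-values must lie in (0,1]")
  o <- order(pvals)
  raw <- pvals[o] * m_total / seq_len(k)
  adj <- pmin(rev(cummin(rev(raw))), 1)
  out <- numeric(k)
  out[o] <- adj
  out
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error level in (0,1).
#' @param n_tests number of tests.
#' @return `alpha / n_tests` (report at two significant figures in
#'   summaries).
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must lie in (0,1)")
  if (n_tests < 1) stop_input("n_tests must be at least 1")
  alpha / n_tests
}

#' Test every score against one outcome
#'
#' Convenience loop over the columns of a score matrix, fitting the
#' per-outcome model and BH-adjusting the resulting p-values as one family
#' (optionally against a larger `m_total`).
#'
#' @param scores a [compute_scores()] result or plain matrix.
#' @param phenotypes phenotype table.
#' @param outcome one of `"risk", "OS", "CSS", "RFS"`.
#' @param spec a [model_spec()].
#' @param m_total family size for BH adjustment (default: number of scores
#'   tested).
#' @return data.frame of association rows with `fdr_pval` filled in.
#' @export
associate_scores <- function(scores, phenotypes, outcome = "risk",
                             spec = model_spec(), m_total = NULL) {
  vals <- if (inherits(scores, "score_matrix")) scores$values else as.matrix(scores)
  res <- do.call(rbind, lapply(colnames(vals), function(id) {
    if (outcome == "risk")
      fit_risk_model(vals[, id], phenotypes, spec, score_id = id)
    else
      fit_survival_model(vals[, id], phenotypes, spec, outcome, score_id = id)
  }))
  ok <- !is.na(res$pval)
  if (any(ok))
    res$fdr_pval[ok] <- bh_adjust(res$pval[ok], m_total %||% sum(ok))
  res
}
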