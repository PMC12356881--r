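---
title: "LD-adjusted mQTL genotypic scores: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LD-adjusted mQTL genotypic scores: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mqtlscore)
```

## The model

A methylation quantitative trait locus (mQTL) score predicts the
methylation level of one CpG probe from genotype. Given marginal
summary-statistic effects $\beta_t$ for probe $t$ over the SNPs of one
trait-associated region, and the SNP–SNP correlation matrix $R$ estimated
from a reference panel, the score of individual $i$ is

$$\mathrm{score}(i,t) = g_i^{\top} R^{-1} \beta_t,$$

with $g_i$ the individual's dosage vector. Multiplying by $R^{-1}$
converts marginal effects into approximately joint effects, so that SNPs
carrying the same signal through LD are not double-counted. The score is
a linear predictor of methylation, and testing it against an outcome asks
whether genetically predicted methylation of that probe associates with
the outcome.

Downstream of scoring, the package fits one model per score: logistic
regression for case-control risk and stratified Cox models for overall
survival (OS), cancer-specific survival (CSS; deaths from other causes
censored) and recurrence-free survival (RFS; non-recurrent patients
censored at death or end of follow-up), adjusted for age, sex and ten
principal components and stratified by AJCC stage. Wald statistics give
the p-values, matching the estimate/SE/p triplets such analyses report.
Multiplicity is controlled per outcome family by the Benjamini–Hochberg
step-up procedure; `bh_adjust()` accepts a family size `m_total` larger
than the number of supplied p-values so that the published top of a much
larger scan can be re-adjusted from printed values alone.

Colocalisation of an mQTL signal with a disease-GWAS signal uses the
approximate-Bayes-factor model under the single-causal-variant-per-trait
assumption. Each SNP's Wakefield log-ABF is
$\tfrac12[\log(1-r) + r z^2]$ with $z=\beta/\mathrm{se}$ and
$r = s_0^2/(s_0^2+\mathrm{se}^2)$; per-SNP ABFs combine into likelihood
sums for the five hypotheses (no association; one trait only; both,
distinct variants; both, shared variant), weighted by priors and
normalised. PP(H4) above 0.80 declares a shared causal variant, and the
SNP maximising the per-SNP H4 weight is reported as the top colocalised
SNP.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `p_seed` | 1e-6 | a region must contain one SNP below this p-value |
| `p_include` | 1e-5 | SNPs below this p-value join the region |
| `min_separation` | 1 Mb | minimum gap between regions of one probe |
| `ridge` | 0.01 | shrinkage weight of $R$ towards the identity |
| `prune_threshold` | 0.90 | score-correlation exclusion cut-off |
| `maf_min` | 0.0005 | minor-allele-frequency QC floor (0.05 %) |
| `hwe_p_min` | 1e-5 | Hardy–Weinberg exact-test floor |
| `info_min` | 0.80 | imputation-quality floor |
| `callrate_min` | 0.95 | per-variant call-rate floor |
| `p1`, `p2`, `p12` | 1e-4, 1e-4, 1e-5 | per-SNP colocalisation priors |
| `prior_sd_quant`, `prior_sd_cc` | 0.15, 0.2 | prior effect scales (quantitative / log-odds) |
| `min_overlap` | 10 | minimum shared variants for colocalisation |
| `pph4_call` | 0.80 | PP(H4) threshold for a colocalisation call |

Distance classification of a score relative to its probe's gene span uses
0 distance on overlap, the minimal gap otherwise: `cis` below 50 kb,
`cis-x` from 50 kb to 5 Mb, `trans` beyond or on another chromosome.
The default MAF floor of 0.05 % is unusually low for a variant QC filter;
it is the documented default here and an explicit argument, so analyses
preferring a conventional 1–5 % floor simply pass it.

## Design choices where the design was open

* **Ridge regularisation, λ = 0.01.** Regions can hold hundreds to over a
  thousand SNPs, where a finite panel's correlation matrix is
  rank-deficient, so some regularisation is unavoidable. Shrinking as
  $(1-\lambda)R + \lambda I$ preserves the unit diagonal; λ = 0
  reproduces the exact solve on well-conditioned regions, and weights are
  obtained by a linear solve, never an explicit inverse, with a residual
  check of $\|Rw-\beta\|_\infty$.
* **Missing-SNP policy.** SNPs absent from the cohort are dropped from
  the definition and the weights re-solved on the re-subset $R$ — not
  zero-imputed — keeping $w$ consistent with the $\beta$ actually used.
* **Pruning order.** Only "highly correlated scores are excluded" is
  specified by convention; the keep-rule here is greedy by the region's
  smallest member p-value, most significant first, which makes the
  retained set well-defined and order-invariant. Score correlation is
  computed in-cohort (a panel-based alternative is a one-line change in
  calling code, since pruning operates on any score matrix).
* **HLA span.** chr6:25–35 Mb by common convention, configurable.
* **Related pairs.** Exclude the control of a case-control pair, else
  the lower-call-rate member, with a lexicographic tie-break so the rule
  is deterministic.
* **Palindromic variants** (A/T, C/G) are removed during harmonization
  rather than frequency-rescued: deterministic and conservative.
* **Dosages vs hard calls.** Scores use dosages when a VCF `DS` field is
  present; the Hardy–Weinberg exact test runs on rounded hard calls,
  since the exact test is defined on genotype counts.
* **FDR families.** Adjustment is per outcome family (risk, OS, CSS,
  RFS separately), since an adjusted threshold "varies by outcome" only
  under per-outcome adjustment.
* **Region separation is enforced per probe**, consistent with scores
  being probe-specific; two probes may have overlapping regions.
* **Tie handling in Cox models** is Efron's approximation.
* **Survival testing is two-tier by default**: survival and recurrence
  models run on the risk-significant set, with a `genomewide_survival`
  flag for scanning every score.

## What the synthetic generator emulates — and what it does not

The generator exists so that every downstream stage is testable without
restricted data. Haplotypes follow a first-order copying process within
LD blocks: allele $j$ copies allele $j-1$ with probability `ld_decay`,
else is drawn fresh at its own frequency. This yields monotone,
geometrically decaying LD within blocks and independence across blocks —
enough structure for LD-adjustment, pruning and colocalisation to be
exercised, with positions spaced 1 kb so the 1 Mb/50 kb/5 Mb distance
rules are reachable by scaling. Methylation phenotypes are linear in a
few causal dosages plus unit-variance noise, and the exported summary
statistics are per-SNP marginal OLS on the panel, so they carry the same
estimator noise a meta-analysis export would. Case-control status is
logistic in the standardised genetic value of designated probes with the
intercept tuned numerically to the target case fraction; survival and
recurrence times are exponential with multiplicative hazards (the
simplest model satisfying the proportional-hazards assumption the Cox
stage fits) under independent exponential censoring; stage is drawn
independently of genotype by default, with a configurable logistic tilt
of the stage-IV probability for confounded regimes.

Defaults describe a moderate European-ancestry case-control study: case
fraction 0.35, baseline hazard 0.08/year against censoring at 0.04/year
(about a third of cases die over follow-up, roughly 70 % of those from
the disease), stage probabilities (0.20, 0.35, 0.30, 0.15), case/control
ages 63/59 years and male fractions 0.57/0.46, allele frequencies uniform
on (0.05, 0.5) and `ld_decay` 0.9.

The generator does **not** emulate: real LD (no recombination hotspots,
no long-range structure, one chromosome per block), realistic
allele-frequency spectra, the 450k/EPIC probe catalogue or real per-probe
SNP-count distributions (1 to >1500 in real scores; here block size is
the knob), population stratification (PCs are simulated independent of
genotype), cell-type heterogeneity, or array/imputation artefacts beyond
an `info` column. Passing tests therefore demonstrate the statistical
machinery — estimator consistency, error control, scenario recovery —
not robustness to the confounding structure of real cohorts.

## Numerical choices

* Colocalisation is computed entirely in log space with a stable
  log-sum-exp; the H3 cross term $S_1 S_2 - S_{12}$ uses
  `log1p(-exp(d))` guarded against cancellation, and equals naive
  arithmetic to 1e-9 whenever naive arithmetic does not overflow.
* The HWE exact test enumerates all heterozygote counts compatible with
  the allele counts in log-factorial space and normalises, summing
  probabilities no greater than the observed one (with a 1e-9 relative
  slack against ties lost to rounding).
* BH adjustment is the textbook step-up with running minima; ties in the
  input map to equal adjusted values.
* Degenerate association inputs (constant score, single outcome class,
  zero events, separation) return flagged rows rather than exceptions,
  so a scan never aborts mid-family.
* Region partitioning resolves duplicate positions only when allele
  pairs agree; conflicting duplicates are an input error.

## Problem sizes used by the test suite

Worked-example checks are instantaneous. Simulation suites use panels of
300–2,000 samples, cohorts up to 5,000, 50 replicates for parameter
recovery (planted log-OR 0.4, log-HR 0.3), 200 single-SNP null scores
for type-I error, and 25–30 replicates per colocalisation scenario at
40 SNPs and 2,000 panel samples — sizes chosen so the full suite runs in
about a minute on one core while keeping Monte-Carlo error well inside
the asserted tolerances.

## Known limitations

Single-causal-variant colocalisation cannot represent regions with
multiple shared variants (no SuSiE-style extension); the score model
assumes the summary-statistic and cohort populations share LD; ridge
shrinkage trades a small bias in $w$ for invertibility and is not
cross-validated; no genotype imputation, phasing or ancestry inference
is provided; and the stage-IV subanalysis requires observed stage with
at least two categories.
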