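---
title: "Methods: blood miRNA survival signatures, from discovery to deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blood miRNA survival signatures, from discovery to deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirisk)
```

## The problem

Whole blood collected in PAXgene tubes yields a mixed-cell small RNA
profile. In stage IV NSCLC under PD-1 inhibitor monotherapy, linear
combinations of a handful of log-transformed miRNA abundances are
prognostic for overall survival; the published five-miRNA miRisk score is
the canonical example, and its evaluation against PD-L1 tumor proportion
score (TPS) requires time-dependent ROC analysis under censoring. This
package provides the complete modelling stack — survival statistics,
signature discovery, clinical evaluation, cell-of-origin deconvolution and
qPCR concordance — together with a synthetic cohort generator that makes
every stage testable against planted ground truth.

## Survival core

### Cox proportional hazards

`fit_cox()` maximizes the log partial likelihood by Newton–Raphson with
step-halving. Both the Efron (default) and Breslow corrections for tied
event times are implemented; Efron is the default because it is the better
approximation under heavy ties, while Breslow is retained because the
two-group score test at β = 0 with Breslow weights is algebraically the
log-rank statistic whenever event times are untied — an identity the test
suite checks to 1e-6 on its exact domain and which the forward-selection
objective exploits for speed (tied data take the general log-rank path;
with tied deaths the log-rank variance carries a hypergeometric
multiplicity factor that the score information does not, so the two
statistics genuinely differ there). Standard errors come from the
inverse observed information; 95% intervals are Wald, `exp(β ± 1.96·SE)`,
matching the usual HR/CI presentation of clinical covariate tables.
Convergence tolerances are fixed (score < 1e-7 or step < 1e-9, at most 100
iterations, step-halving on any likelihood decrease) so fits are
deterministic across platforms. Monotone likelihoods (a covariate that
perfectly separates risk) are reported as errors once |β| exceeds 20 rather
than returned as huge pseudo-estimates.

### Kaplan–Meier, log-rank, concordance

`km_estimate()` is the product-limit estimator; censored observations leave
the risk set without producing steps. `logrank_test()` accumulates
observed-minus-expected events with the hypergeometric variance, for any
number of groups. `concordance_index()` is Harrell's C over admissible
pairs (the earlier member observed to fail; risk ties count 0.5).

### IPCW time-dependent ROC

`ipcw_auc()` implements the cumulative-cases / dynamic-controls AUC at a
fixed horizon (6 months in this literature) with inverse probability of
censoring weights. The censoring survival function G is the Kaplan–Meier
estimate treating censorings as events; cases entering at time T are
weighted 1/G(T−) (left-limit convention) and controls 1/G(horizon). Without
censoring all weights are equal and the estimator reduces exactly to the
Mann–Whitney AUC, which the tests assert identically. The AUC's 95%
interval, where needed, comes from the patient-level bootstrap
(`bootstrap_auc_difference()`), which is also how differences between two
markers' AUCs are assessed: percentile 2.5/97.5 over 1000 resamples by
default, resamples that lose all cases or controls being redrawn so the
effective number of draws is preserved.

## Signature discovery

Discovery follows filter-then-wrap: first a univariable Cox screen keeping
features with Wald p < 0.05 (a per-comparison false positive rate by
design — a null screen of m features retains about 0.05·m), then greedy
sequential forward selection. Each candidate addition is scored by 5-fold
cross-validation: fit the multivariable Cox model on the training folds,
score held-out samples with the linear predictor, pool all out-of-fold
scores, split at their median, and take the two-group log-rank p. The
candidate minimizing this p is added; the final size is the element of
`k_grid` (default 1..10) with the smallest CV p, ties broken toward the
smaller model. Folds are event-stratified so every training set carries
events, and the fold seed is explicit, making the whole procedure
idempotent for fixed inputs. Non-convergent univariable fits are excluded
rather than assigned p = 1, mirroring the requirement that a model *could
be fit* to the feature.

The fitted signature stores `(miRNA, weight)` pairs — the multivariable Cox
coefficients on the full training set — with the fixed transform
`ln(RPM + 1)` and a cutpoint equal to the median training score. Natural
log is used throughout (consistent with the magnitude of the published
cutpoint); stratification is strict (`score > cutpoint` is high risk), so
the median sample of an odd cohort lands in the low-risk group and ties are
deterministic. The published miRisk instance ships as a JSON asset with its
printed coefficients and cutpoint 5.61 and is never re-estimated.

## Clinical evaluation

`cox_covariate_table()` applies the fixed dichotomizations of the clinical
covariates (PD-L1 TPS ≥50%; ECOG >0; male sex; age >75; therapy line >2;
pembrolizumab vs nivolumab; non-adenocarcinoma histology; ever-smoker;
ANC >7.5; ALC >1) in univariable or joint multivariable mode, with
listwise NA exclusion per fit. `pd_l1_marker()` codes the TPS trichotomy
ordinally (<1 → 0, 1–49 → 1, ≥50 → 2) for ROC use; `combined_model()`
refits a Cox model over the signature miRNAs plus this ordinal term to ask
whether PD-L1 adds information beyond the miRNAs.

`cohort_characteristics()` reproduces Table-1-style cohort comparisons:
Pearson χ² per categorical variable — with Yates continuity correction for
2×2 tables only, which is the variant that reproduces the published
p-values from the printed counts — and a two-sided Welch t-test for age.
NA rows are excluded per variable. The published counts themselves are
packaged (`nsclc_table1_counts()`) as inputs for `table1_statistics()`.
Two published rows (ECOG, PD-L1) are not reproducible by either χ² variant
from the printed counts; their test variant is ambiguous and they are
deliberately not asserted anywhere.

`permutation_importance()` measures a feature's contribution as the drop in
Harrell's C when that feature's column is randomly shuffled (seeded,
averaged over repeats), which is the model-agnostic importance used with
external survival learners; no survival forest is trained here.

## Deconvolution

For a sorted-cell atlas of C = 10 blood cell populations from P donors, the
scaling factor per cell type c and donor p is

> α = (V_elution · c_sRNA / n_sorted) · n_blood,

the small RNA yield per sorted cell scaled by the cell type's abundance per
ml of blood (units: ng small RNA per ml). Scaled means are averaged across
donors, and each miRNA's cell-type proportions are its row-normalized
scaled means. Proportions are invariant to any global rescaling of α and to
rescaling all donors' expression by a constant. miRNAs absent from the
atlas (zero scaled total) are flagged "unattributed", never silently
dropped. Dominant-cell assignment is the argmax, with ties broken by the
fixed canonical order (erythrocytes, platelets, neutrophils, eosinophils,
basophils, monocytes, NK, CD4 T, CD8 T, B) for determinism.
`expression_count_correlation()` relates whole-blood miRNA RPM to clinical
blood counts per cell type with Pearson r, excluding samples more than
`exclusion_sd` (default 5) SDs above the mean count — the rule that
excluded one extreme-monocyte sample in the motivating analysis.

## Assay concordance

Housekeeper assays are chosen as the k lowest-variance features of
`log2(RPM+1)` among features with median RPM above a floor. ΔCt subtracts
the mean housekeeper Ct from each replicate-averaged target Ct (invariant
to per-sample plate shifts); ΔΔCt is the high-minus-low group difference
and the reported fold change is 2^(−ΔΔCt), so FC > 1 means higher
expression in the high-risk group. Group tests are Welch by default — the
unpaired two-tailed convention — and the fold change is returned even when
a group is too small to test. `blocking_efficiency()` compares paired
unblocked/blocked libraries: per-sample and pooled target read fractions,
the percent reduction `100·(1 − blocked/unblocked)` of the pooled fraction,
and the Pearson r of mean log2 RPM across non-target miRNAs detected in
both conditions.

## The synthetic cohort generator

The generator's defaults encode the study conditions the analysis assumes:

* **Expression.** 2000 miRNA features, three dominant erythroid-like
  features (named miR-486-5p, miR-451a, miR-16-5p) jointly carrying 50% of
  each sample's reads — the unblocked whole-blood regime — with the
  remaining features log-normal (σ = 1) around per-feature baseline
  abundances. Baselines are drawn under a fixed internal seed so that
  cohorts simulated with different seeds share one population expression
  profile, as independent clinical cohorts do; only sampling noise is
  seed-specific. Rows are closed to 1e6 RPM exactly.
* **Survival.** Exponential event times with hazard
  `0.05·exp(lp − mean(lp))` events/month — median OS near 14 months, the
  right scale for stage IV NSCLC — where lp places weight 0.8 on each of 5
  planted features of `ln(RPM+1)`. The exponential (rather than Weibull)
  choice gives the closed-form identity β = log HR used by the
  parameter-recovery oracles. Censoring is administrative, uniform on
  (0, 36) months, yielding roughly 40–50% censoring; the generator records
  the intended censoring proportion as documentation, and the published
  cohorts' actual censoring pattern is unknown, so this is a stand-in, not
  an inference. `accrual_months = Inf` disables censoring.
* **Clinical covariates** follow the training cohort's printed marginal
  frequencies (e.g. PD-L1 ≥50% in 68/96) through a Gaussian copula that can
  correlate them with the planted predictor without distorting the
  marginals; association 0 gives exact independence from outcome.
* **Atlas.** 10 cell types × 12 donors, per-library RPM, with a leading
  block of miRNAs expressed in exactly one cell type as planted
  cell-of-origin truth, and metadata (18 µl elution, log-normal small-RNA
  concentrations and sorted counts, physiologic blood concentrations per
  cell type) feeding the scaling factors.
* **qPCR.** `Ct = 40 − log2(RPM+1) + N(0, 0.25)` in triplicate.

What the generator does *not* emulate: read-level structure (UMIs,
isomiRs), batch effects between cohorts, correlated miRNA co-expression
modules, and non-proportional hazards. Passing tests therefore demonstrate
correctness of the statistical machinery and recoverability of planted
effects under the stated model — not clinical performance on real cohorts.

## Problem sizes and numerical choices

The heavy validation experiments run discovery on cohorts of n = 300 with
2000 features and 5-fold CV over sizes 1..10, twenty times with fresh
seeds, and validate each discovered signature on an independent n = 300
cohort; single-coefficient recovery uses n = 500. One global integer seed
feeds each generator function through documented offsets, so any cohort is
bit-reproducible. All randomized routines (folds, bootstrap, permutation
importance) take explicit seeds and restore the caller's RNG state.

Degenerate inputs are errors, not silent repairs: constant covariates,
missing signature miRNAs (never imputed to zero), horizons with no cases or
controls, atlases with incomplete metadata grids, and housekeeper floors
that exclude everything all fail loudly with named diagnostics.

## Known limitations

* The discovery pipeline inherits greedy forward selection's instability:
  with correlated features the selected set varies across seeds even when
  the planted features are recovered; the cross-model consistency checked
  in the tests (a majority of planted features recovered per run) is the
  realistic expectation, not exact set recovery.
* Signature sizes chosen by the CV objective tend toward the upper end of
  `k_grid` when many filtered null features remain available, because
  spurious additions are only weakly penalized by the median-split
  objective; parsimony enters only through tie-breaking.
* The IPCW estimator assumes censoring independent of the marker;
  informative censoring would bias the 6-month AUCs.
* Proportion-based deconvolution attributes expression, it does not
  estimate mixture fractions; regression-based deconvolution is out of
  scope.
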