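# mirisk

Blood-based miRNA survival signatures for immunotherapy outcome prediction.

Whole-blood small RNA profiles carry information about the systemic immune
state of cancer patients. In advanced non-small cell lung cancer (NSCLC)
treated with PD-1 inhibitors, a five-miRNA risk score measured in PAXgene
whole blood — the **miRisk score** — stratifies overall survival (OS) better
than the tissue-based PD-L1 tumor proportion score. This package implements
the full analysis stack behind such signatures:

* **Survival core, written from scratch** — Cox proportional hazards by
  Newton–Raphson on the partial likelihood (Efron and Breslow tie handling),
  Kaplan–Meier estimation, the log-rank test, Harrell's concordance index,
  and IPCW (inverse probability of censoring weighted) time-dependent ROC
  AUC with cumulative cases / dynamic controls.
* **Signature discovery** — univariable Cox filter at per-comparison
  p < 0.05, then cross-validated sequential forward selection that greedily
  adds features minimizing the out-of-fold median-split log-rank p, and a
  final multivariable fit with a median risk-score cutpoint.
* **The frozen miRisk score** — shipped as a JSON asset with the published
  coefficients and cutpoint:

  ```
  miRisk = 1.870·ln(miR-2115-3p + 1) + 0.907·ln(miR-218-5p + 1)
         + 0.495·ln(miR-224-5p + 1) + 1.309·ln(miR-4676-3p + 1)
         + 1.159·ln(miR-6503-5p + 1)        (RPM inputs; cutpoint 5.61)
  ```

* **Evaluation** — group HR/CI/log-rank comparisons, uni-/multivariable
  clinical covariate tables with fixed dichotomizations, bootstrap
  comparison of time-dependent AUCs (e.g. miRisk vs PD-L1 TPS),
  permutation feature importance by concordance reduction, and
  Table-1-style cohort-characteristics testing (χ², Welch t).
* **Cell-of-origin deconvolution** — scaling of a sorted-cell miRNA atlas by
  per-donor small-RNA yield and blood abundance
  (α = V_elution·c_sRNA/n_sorted · n_blood), donor-averaged scaled means,
  per-miRNA cell-type proportions and dominant-cell assignment.
* **Assay concordance** — ΔCt/2^(−ΔΔCt) qPCR fold changes with low-variance
  housekeeper selection, and blocking-efficiency statistics for libraries in
  which the dominant erythroid miRNAs (miR-486-5p, miR-451a, miR-16-5p) are
  suppressed.
* **A seeded synthetic cohort generator** that emulates the data structure
  all of the above assumes (erythroid read dominance, planted survival
  effects, Table-1-like covariates, sorted-cell atlas, triplicate Ct
  values), so the entire pipeline is testable without access to patient
  data.

## Worked example

```r
library(mirisk)

## a synthetic training cohort: 300 patients, 2000 miRNAs, five planted
## survival-associated features with log-HR weight 0.8
cfg   <- sim_config(n_samples = 300, seed = 11)
train <- simulate_cohort(cfg)

disc <- discover_signature(train$expression, train$survival,
                           selection_config(cv_seed = 11))
disc$signature
#> miRNA risk signature (10 features, transform ln1p)
#>         mirna  weight
#>    miR-224-5p  0.6634
#>   miR-6503-5p  0.7108
#>  miR-sim-1470  0.1958
#>    miR-218-5p  0.4366
#>  miR-sim-0193  0.2208
#>  miR-sim-1501  0.1516
#>  miR-sim-0539 -0.0126
#>  miR-sim-0973  0.0196
#>  miR-sim-1577  0.1081
#>  miR-sim-1067 -0.0117
#> cutpoint: 9.0017 - discovered: FPR filter + CV forward selection

## independent validation cohort from the same generator
valid  <- simulate_cohort(sim_config(n_samples = 300, seed = 99))
scores <- signature_score(disc$signature, valid$expression)
compare_groups_survival(stratify(scores, disc$signature$cutpoint),
                        valid$survival)
#> Group survival comparison (n = 135 / 165)
#> HR 4.64 (95% CI 3.23-6.67), log-rank p = 2.96e-19
```

The high-risk group (scores above the training-median cutpoint) dies ~4.6×
faster in the independent cohort: the pipeline generalizes under the
generator's planted 0.8 log-hazard weights. The frozen published score is
evaluated the same way:

```r
scores <- mirisk_score(expression_rpm)      # needs the 5 miRisk miRNAs
groups <- stratify(scores, mirisk_signature()$cutpoint)   # 5.61
```

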