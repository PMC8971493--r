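#' Compare survival between two risk groups
#'
#' Hazard ratio (high vs low, high coded 1) from univariable Cox regression,
#' log-rank p-value and per-group Kaplan-Meier curves.
#'
#' @param labels Factor or vector with exactly two groups; with levels
#'   `low`/`high` the HR is high vs low, otherwise the second factor level is
#'   coded 1.
#' @inheritParams fit_cox
#' @return List of class `group_comparison`: `hr`, `ci95`, `logrank_p`,
#'   `cox_fit`, `km_curves` (named list per group), `n_per_group`.
#' @export
compare_groups_survival <- function(labels, survival, ties = "efron") {
  surv <- as_survival_data(survival)
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2L) {
    stop("grouping error: exactly two non-empty groups required",
         call. = FALSE)
  }
  x <- matrix(as.numeric(labels == levels(labels)[2L]),
              dimnames = list(NULL, paste0(levels(labels)[2L], "_vs_",
                                           levels(labels)[1L])))
  fit <- fit_cox(x, surv, ties = ties)
  lr <- logrank_test(labels, surv)
  kms <- lapply(split(seq_len(nrow(surv)), labels),
                function(i) km_estimate(surv[i, ]))
  structure(list(hr = unname(fit$hazard_ratios[1L]),
                 ci95 = unname(fit$ci95[1L, ]),
                 logrank_p = lr$p_value, cox_fit = fit, km_curves = kms,
                 n_per_group = table(labels)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group survival comparison (n = ",
      paste(x$n_per_group, collapse = " / "), ")\n", sep = "")
  cat("HR ", round(x$hr, 2), " (95% CI ", round(x$ci95[1], 2), "-",
      round(x$ci95[2], 2), "), log-rank p = ", signif(x$logrank_p, 3),
      "\n", sep = "")
  invisible(x)
}

# Fixed dichotomisation rules for the clinical covariate table.
dichotomize_clinical <- function(clinical, risk_labels = NULL) {
  out <- data.frame(row.names = rownames(clinical))
  cc <- function(v) as.numeric(v)
  if (!is.null(clinical$pd_l1_category)) {
    out[["PD-L1 (>=50%)"]] <- cc(pd_l1_marker(clinical) == 2)
  }
  if (!is.null(clinical$ecog)) {
    ecog <- suppressWarnings(as.numeric(as.character(clinical$ecog)))
    out[["ECOG (>0)"]] <- cc(ecog > 0)
  }
  if (!is.null(clinical$sex)) {
    out[["Sex (male vs female)"]] <- cc(clinical$sex == "male")
  }
  if (!is.null(clinical$age)) out[["Age (>75 years)"]] <- cc(clinical$age > 75)
  if (!is.null(clinical$therapy_line)) {
    out[["Therapy line (>2)"]] <- cc(clinical$therapy_line > 2)
  }
  if (!is.null(clinical$substance)) {
    out[["Substance (pembro vs nivo)"]] <- cc(clinical$substance == "pembrolizumab")
  }
  if (!is.null(clinical$histology)) {
    out[["Histology (non-adeno vs adeno)"]] <- cc(clinical$histology != "adeno")
  }
  if (!is.null(clinical$smoking)) {
    out[["Smoking (ever vs other)"]] <- cc(clinical$smoking %in% c("former", "current"))
  }
  if (!is.null(clinical$anc)) out[["ANC (>7.5)"]] <- cc(clinical$anc > 7.5)
  if (!is.null(clinical$alc)) out[["ALC (>1)"]] <- cc(clinical$alc > 1)
  if (!is.null(risk_labels)) {
    out[["miRisk (high vs low)"]] <- as.numeric(risk_labels == "high")
  }
  out
}

#' Uni- and multivariable Cox covariate table
#'
#' Applies the fixed dichotomisations (PD-L1 >=50%; ECOG >0; male sex;
#' age >75; therapy line >2; pembrolizumab vs nivolumab; non-adeno histology;
#' ever-smoker; ANC >7.5; ALC >1; optional high vs low risk label) and fits
#' either one univariable Cox model per covariate or a single joint
#' multivariable model. Samples with NA in a used covariate are dropped for
#' that fit (univariable) or listwise (multivariable); covariates constant
#' after dichotomisation are dropped with a warning, and a univariable
#' covariate whose fit is not estimable (e.g. a rare stratum that perfectly
#' separates risk) yields an NA row with a warning rather than aborting the
#' table.
#'
#' @param clinical Clinical covariate data.frame (see [simulate_clinical()]
#'   for the column vocabulary).
#' @param risk_labels Optional risk-group factor added as `miRisk` covariate.
#' @inheritParams fit_cox
#' @param mode `"univariable"` or `"multivariable"`.
#' @return data.frame with one row per covariate: `covariate`, `hr`,
#'   `ci_lower`, `ci_upper`, `p_value`, `n_used`.
#' @export
cox_covariate_table <- function(clinical, risk_labels = NULL, survival,
                                mode = c("univariable", "multivariable"),
                                ties = "efron") {
  mode <- match.arg(mode)
  surv <- as_survival_data(survival)
  x <- dichotomize_clinical(clinical, risk_labels)
  keep <- vapply(x, function(v) {
    u <- unique(v[!is.na(v)])
    length(u) >= 2L
  }, logical(1))
  if (any(!keep)) {
    warning("dropping constant covariate(s): ",
            paste(names(x)[!keep], collapse = ", "), call. = FALSE)
    x <- x[, keep, drop = FALSE]
  }
  res <- list()
  if (mode == "univariable") {
    for (nm in names(x)) {
      ok <- !is.na(x[[nm]])
      fit <- tryCatch(
        fit_cox(matrix(x[[nm]][ok], dimnames = list(NULL, nm)),
                surv[ok, ], ties = ties),
        error = function(e) {
          warning("covariate ", nm, " not estimable: ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      res[[nm]] <- if (is.null(fit)) {
        data.frame(covariate = nm, hr = NA_real_, ci_lower = NA_real_,
                   ci_upper = NA_real_, p_value = NA_real_,
                   n_used = sum(ok))
      } else {
        data.frame(covariate = nm,
                   hr = unname(fit$hazard_ratios[1L]),
                   ci_lower = fit$ci95[1L, "lower"],
                   ci_upper = fit$ci95[1L, "upper"],
                   p_value = unname(fit$wald_p[1L]),
                   n_used = sum(ok))
      }
    }
  } else {
    ok <- stats::complete.cases(x)
    fit <- fit_cox(as.matrix(x[ok, , drop = FALSE]), surv[ok, ], ties = ties)
    for (nm in names(x)) {
      res[[nm]] <- data.frame(covariate = nm,
                              hr = unname(fit$hazard_ratios[nm]),
                              ci_lower = fit$ci95[nm, "lower"],
                              ci_upper = fit$ci95[nm, "upper"],
                              p_value = unname(fit$wald_p[nm]),
                              n_used = sum(ok))
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Ordinal PD-L1 TPS marker
#'
#' Codes the trichotomised tumor proportion score `<1` -> 0, `1-49` -> 1,
#' `>=50` -> 2 for use as an ROC marker and in combined models.
#'
#' @param clinical Clinical table with a `pd_l1_category` column (or a bare
#'   vector of categories).
#' @return Integer vector in {0, 1, 2}.
#' @export
pd_l1_marker <- function(clinical) {
  v <- if (is.data.frame(clinical)) clinical$pd_l1_category else clinical
  v <- as.character(v)
  # tolerate unicode variants of the category labels
  v[v %in% c("≥50", ">=50")] <- ">=50"
  v[v %in% c("1–49", "1-49")] <- "1-49"
  code <- c("<1" = 0L, "1-49" = 1L, ">=50" = 2L)
  bad <- setdiff(unique(v[!is.na(v)]), names(code))
  if (length(bad)) {
    stop("vocabulary error: unknown PD-L1 category: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(code[v])
}

#' Bootstrap comparison of two time-dependent AUCs
#'
#' Point estimates are IPCW AUCs of each marker at the horizon; the
#' difference `auc_a - auc_b` gets a percentile bootstrap confidence interval
#' over `n_boot` patient resamples (both AUCs recomputed per resample).
#' Resamples with no cases or no controls at the horizon are redrawn so that
#' `n_boot` effective draws enter the interval.
#'
#' @param marker_a,marker_b Per-sample marker vectors of equal length.
#' @inheritParams ipcw_auc
#' @param n_boot Number of bootstrap resamples (study value 1000).
#' @param seed Integer seed for the resampling.
#' @return List of class `auc_comparison`: `horizon`, `auc_a`, `auc_b`,
#'   `delta`, `delta_ci95`, `n_boot`, `n_redrawn`, `seed`.
#' @export
bootstrap_auc_difference <- function(marker_a, marker_b, survival, horizon,
                                     n_boot = 1000L, seed = 1L) {
  if (length(marker_a) != length(marker_b)) {
    stop("input error: markers must have equal length", call. = FALSE)
  }
  surv <- as_survival_data(survival)
  auc_a <- ipcw_auc(marker_a, surv, horizon)$auc
  auc_b <- ipcw_auc(marker_b, surv, horizon)$auc
  n <- nrow(surv)
  deltas <- numeric(n_boot)
  n_redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        d <- tryCatch({
          ipcw_auc(marker_a[idx], surv[idx, ], horizon)$auc -
            ipcw_auc(marker_b[idx], surv[idx, ], horizon)$auc
        }, error = function(e) NULL)
        if (!is.null(d)) break
        n_redrawn <- n_redrawn + 1L
      }
      deltas[b] <- d
    }
  })
  structure(list(horizon = horizon, auc_a = auc_a, auc_b = auc_b,
                 delta = auc_a - auc_b,
                 delta_ci95 = unname(stats::quantile(deltas, c(0.025, 0.975),
                                                     type = 7)),
                 n_boot = n_boot, n_redrawn = n_redrawn, seed = seed),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat("AUC comparison at ", x$horizon, " months: ", round(x$auc_a, 3),
      " vs ", round(x$auc_b, 3), "; delta = ", round(x$delta, 3),
      " (95% bootstrap CI ", round(x$delta_ci95[1], 3), " to ",
      round(x$delta_ci95[2], 3), ", ", x$n_boot, " resamples)\n", sep = "")
  invisible(x)
}

#' Combined signature + PD-L1 Cox model
#'
#' Retrains a multivariable Cox model over the signature miRNAs plus the
#' ordinal PD-L1 marker and returns the result as a signature whose feature
#' list includes the PD-L1 term (feature name `PD-L1`). Scoring such a
#' signature requires a feature matrix carrying a `PD-L1` column (see
#' examples).
#'
#' @param features Transformed feature matrix restricted to (at least) the
#'   signature miRNAs.
#' @param pd_l1 Ordinal PD-L1 marker from [pd_l1_marker()].
#' @param signature_features Names of the signature miRNAs to include.
#' @inheritParams fit_cox
#' @return A `mirna_signature` with an extra `PD-L1` feature.
#' @export
combined_model <- function(features, pd_l1, survival,
                           signature_features = mirisk_signature()$features$mirna,
                           ties = "efron") {
  x <- as_covariate_matrix(features)
  missing <- setdiff(signature_features, colnames(x))
  if (length(missing)) {
    stop("feature error: not in feature matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  xx <- cbind(x[, signature_features, drop = FALSE],
              `PD-L1` = as.numeric(pd_l1))
  fit <- fit_cox(xx, survival, ties = ties)
  scores <- drop(xx %*% fit$coefficients)
  new_signature(data.frame(mirna = colnames(xx),
                           weight = unname(fit$coefficients)),
                cutpoint = stats::median(scores),
                provenance = "combined signature + PD-L1 Cox model",
                fit = fit)
}

#' Permutation feature importance by concordance reduction
#'
#' Importance of a feature is the drop in Harrell's concordance index when
#' the association between that feature and survival is destroyed by randomly
#' shuffling its column: `C(original) - mean over repeats of C(shuffled)`.
#'
#' @param scorer Function mapping a feature matrix to per-sample risk scores
#'   (e.g. `function(x) signature_score(sig, x)` on RPM, or a linear-predictor
#'   closure on transformed features).
#' @param features Feature matrix handed to `scorer`.
#' @inheritParams fit_cox
#' @param n_repeats Shuffles per feature.
#' @param seed Integer seed.
#' @return Named numeric vector of importances (one per feature column).
#' @export
permutation_importance <- function(scorer, features, survival,
                                   n_repeats = 10L, seed = 1L) {
  x <- as.matrix(features)
  surv <- as_survival_data(survival)
  c_full <- concordance_index(scorer(x), surv)
  with_seed(seed, {
    imp <- vapply(seq_len(ncol(x)), function(j) {
      cs <- vapply(seq_len(n_repeats), function(r) {
        xs <- x
        xs[, j] <- xs[sample.int(nrow(x)), j]
        concordance_index(scorer(xs), surv)
      }, numeric(1))
      c_full - mean(cs)
    }, numeric(1))
    stats::setNames(imp, colnames(x))
  })
}
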