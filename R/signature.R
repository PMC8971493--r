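#' Log-transform an RPM expression matrix
#'
#' Elementwise natural log of (RPM + 1); the fixed feature transform of every
#' risk score in this package.
#'
#' @param expression Non-negative RPM matrix, samples x miRNAs.
#' @return Matrix of the same shape, `ln(RPM + 1)`.
#' @export
transform_expression <- function(expression) {
  x <- as.matrix(expression)
  if (any(x < 0)) stop("domain error: RPM values must be >= 0", call. = FALSE)
  log1p(x)
}

#' Univariable Cox false-positive-rate filter
#'
#' Fits a single-covariate Cox model per feature and retains features with
#' Wald p below `alpha`. No multiplicity correction is applied: the filter
#' controls the per-comparison error rate by design, so a null screen of
#' `m` features retains about `alpha * m` of them. Features whose fit does
#' not converge (or is degenerate) are dropped and recorded.
#'
#' @param features Transformed feature matrix (see [transform_expression()]).
#' @inheritParams fit_cox
#' @param alpha Per-feature significance level (study value 0.05).
#' @return List: `selected` (feature names, in column order), `p_values`
#'   (named, NA for non-convergent features), `dropped` (names of features
#'   without a valid fit).
#' @export
univariable_cox_filter <- function(features, survival, alpha = 0.05,
                                   ties = "efron") {
  x <- as_covariate_matrix(features)
  surv <- as_survival_data(survival)
  stopifnot(alpha > 0, alpha <= 1)
  p_values <- stats::setNames(rep(NA_real_, ncol(x)), colnames(x))
  for (j in seq_len(ncol(x))) {
    fit <- tryCatch(fit_cox(x[, j, drop = FALSE], surv, ties = ties),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$converged) p_values[j] <- fit$wald_p[1L]
  }
  dropped <- names(p_values)[is.na(p_values)]
  selected <- names(p_values)[!is.na(p_values) & p_values < alpha]
  list(selected = selected, p_values = p_values, dropped = dropped)
}

#' Selection configuration for signature discovery
#'
#' @param fpr_alpha Univariable filter level (study value 0.05).
#' @param k_grid Candidate signature sizes; ties in the cross-validated
#'   objective are broken toward the smaller size.
#' @param cv_folds Number of event-stratified cross-validation folds.
#' @param cv_seed Seed for fold assignment.
#' @param ties_method Cox tie handling used throughout the selection.
#' @return List of class `selection_config`.
#' @export
selection_config <- function(fpr_alpha = 0.05, k_grid = 1:10, cv_folds = 5L,
                             cv_seed = 1L, ties_method = "efron") {
  stopifnot(fpr_alpha > 0, fpr_alpha < 1, length(k_grid) >= 1, cv_folds >= 2)
  structure(list(fpr_alpha = fpr_alpha, k_grid = sort(unique(as.integer(k_grid))),
                 cv_folds = as.integer(cv_folds), cv_seed = as.integer(cv_seed),
                 ties_method = ties_method),
            class = "selection_config")
}

# Event-stratified fold assignment so every fold carries events.
make_cv_folds <- function(surv, k, seed) {
  with_seed(seed, {
    fold <- integer(nrow(surv))
    for (grp in list(which(surv$event == 1L), which(surv$event == 0L))) {
      if (length(grp)) {
        fold[grp] <- sample(rep_len(seq_len(k), length(grp)))
      }
    }
    fold
  })
}

# Cross-validated median-split log-rank p for one candidate feature set.
# `folds` is a list of per-fold train/test index sets with the training
# survival frames prebuilt (they do not change across candidates). With
# untied event times the median-split log-rank p is computed through the
# Breslow Cox score test on the group indicator — algebraically identical
# there and much faster; tied data take the general log-rank path.
cv_logrank_p <- function(x, surv, folds, ties, untied = FALSE) {
  scores <- rep(NA_real_, nrow(x))
  for (f in folds) {
    fit <- tryCatch(fit_cox(x[f$train, , drop = FALSE], f$train_surv,
                            ties = ties),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    scores[f$test] <- drop(x[f$test, , drop = FALSE] %*% fit$coefficients)
  }
  high <- as.numeric(scores > stats::median(scores))
  if (all(high == high[1L])) return(1)
  tryCatch({
    if (untied) {
      cox_score_test(matrix(high), surv, ties = "breslow")$p_value
    } else {
      logrank_test(high, surv)$p_value
    }
  }, error = function(e) NA_real_)
}

#' Cross-validated sequential forward selection
#'
#' Greedy forward selection of signature features. At each step every
#' remaining candidate is scored by: fit a multivariable Cox model on the
#' training folds (current set plus candidate), score the held-out folds with
#' the linear predictor, pool the out-of-fold scores, split at their median,
#' and take the log-rank p between the pooled low/high groups. The candidate
#' minimising this cross-validated p is added. The final signature size is
#' the `k_grid` value with the smallest CV p, ties broken toward parsimony.
#'
#' @param features Transformed feature matrix, typically pre-filtered with
#'   [univariable_cox_filter()].
#' @inheritParams fit_cox
#' @param config A [selection_config()].
#' @return List: `selected` (ordered names, length `best_k`), `path` (full
#'   greedy order explored), `cv_p` (per explored size), `best_k`.
#' @export
sequential_forward_selection <- function(features, survival, config) {
  stopifnot(inherits(config, "selection_config"))
  x <- as_covariate_matrix(features)
  surv <- as_survival_data(survival)
  require_events(surv)
  fold <- make_cv_folds(surv, config$cv_folds, config$cv_seed)
  folds <- lapply(seq_len(config$cv_folds), function(f) {
    train <- which(fold != f)
    list(train = train, test = which(fold == f),
         train_surv = surv[train, ])
  })
  untied <- !anyDuplicated(surv$time[surv$event == 1L])
  k_max <- min(max(config$k_grid), ncol(x))
  path <- character(0)
  cv_p <- stats::setNames(rep(NA_real_, k_max), seq_len(k_max))
  remaining <- colnames(x)
  for (step in seq_len(k_max)) {
    best_p <- Inf
    best_f <- NA_character_
    for (cand in remaining) {
      p <- cv_logrank_p(x[, c(path, cand), drop = FALSE], surv, folds,
                        config$ties_method, untied = untied)
      if (!is.na(p) && p < best_p) {
        best_p <- p
        best_f <- cand
      }
    }
    if (is.na(best_f)) break
    path <- c(path, best_f)
    remaining <- setdiff(remaining, best_f)
    cv_p[step] <- best_p
  }
  grid <- config$k_grid[config$k_grid <= length(path)]
  pk <- cv_p[grid]
  best_k <- grid[which.min(pk)]  # which.min takes the first (smallest k) tie
  list(selected = path[seq_len(best_k)], path = path, cv_p = cv_p,
       best_k = best_k)
}

#' Fit a risk signature on selected features
#'
#' Weights are the multivariable Cox coefficients on the full training set;
#' the cutpoint is the median training risk score (median split: the median
#' sample itself falls in the low-risk group).
#'
#' @param features Transformed feature matrix.
#' @inheritParams fit_cox
#' @param selected Non-empty character vector of feature names.
#' @param provenance Free-text provenance note stored in the signature.
#' @return Object of class `mirna_signature`: `features` (data.frame with
#'   `mirna`, `weight`), `cutpoint`, `transform` (`"ln1p"`), `provenance`,
#'   `fit` (the underlying `cox_fit`).
#' @export
fit_signature <- function(features, survival, selected, ties = "efron",
                          provenance = "fit on training cohort") {
  if (length(selected) == 0L) stop("`selected` must be non-empty", call. = FALSE)
  x <- as_covariate_matrix(features)
  missing <- setdiff(selected, colnames(x))
  if (length(missing)) {
    stop("feature error: not in feature matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fit <- fit_cox(x[, selected, drop = FALSE], survival, ties = ties)
  scores <- drop(x[, selected, drop = FALSE] %*% fit$coefficients)
  new_signature(data.frame(mirna = selected,
                           weight = unname(fit$coefficients)),
                cutpoint = stats::median(scores), provenance = provenance,
                fit = fit)
}

new_signature <- function(features, cutpoint, provenance, fit = NULL) {
  stopifnot(!anyDuplicated(features$mirna))
  structure(list(features = features, cutpoint = cutpoint,
                 transform = "ln1p", provenance = provenance, fit = fit),
            class = "mirna_signature")
}

#' @export
print.mirna_signature <- function(x, ...) {
  cat("miRNA risk signature (", nrow(x$features), " features, transform ",
      x$transform, ")\n", sep = "")
  print(transform(x$features, weight = round(weight, 4)), row.names = FALSE)
  cat("cutpoint:", round(x$cutpoint, 4), "-", x$provenance, "\n")
  invisible(x)
}

#' Score samples with a signature
#'
#' Evaluates `sum_f weight_f * ln(RPM_f + 1)` per sample. Every signature
#' feature must be present in the expression matrix: a missing feature is an
#' error, never an imputed zero.
#'
#' @param signature A `mirna_signature`.
#' @param expression RPM matrix (samples x miRNAs) or a single named row.
#' @return Named numeric vector of risk scores.
#' @export
signature_score <- function(signature, expression) {
  stopifnot(inherits(signature, "mirna_signature"))
  if (is.null(dim(expression))) {
    # single unnamed-row input: return a bare scalar
    expression <- matrix(expression, nrow = 1L,
                         dimnames = list(NULL, names(expression)))
  }
  missing <- setdiff(signature$features$mirna, colnames(expression))
  if (length(missing)) {
    stop("feature error: signature miRNA(s) absent from expression: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- transform_expression(
    expression[, signature$features$mirna, drop = FALSE])
  drop(x %*% signature$features$weight)
}

#' Stratify risk scores at a cutpoint
#'
#' Scores strictly greater than the cutpoint are labelled high risk; scores
#' at or below it (including the median sample of a median split) are low
#' risk.
#'
#' @param scores Numeric risk scores.
#' @param cutpoint Threshold.
#' @return Factor with levels `low`, `high`.
#' @export
stratify <- function(scores, cutpoint) {
  factor(ifelse(scores > cutpoint, "high", "low"), levels = c("low", "high"))
}

#' Run the full discovery pipeline
#'
#' Transform, univariable FPR filter, cross-validated sequential forward
#' selection, and final signature fit with a median cutpoint.
#'
#' @param expression RPM matrix of the training cohort.
#' @inheritParams fit_cox
#' @param config A [selection_config()].
#' @return List: `signature` (`mirna_signature`), `filter` (filter output),
#'   `sfs` (selection output).
#' @export
discover_signature <- function(expression, survival, config = selection_config()) {
  feats <- transform_expression(expression)
  filt <- univariable_cox_filter(feats, survival, alpha = config$fpr_alpha,
                                 ties = config$ties_method)
  if (length(filt$selected) == 0L) {
    stop("no features pass the univariable filter", call. = FALSE)
  }
  sfs <- sequential_forward_selection(feats[, filt$selected, drop = FALSE],
                                      survival, config)
  sig <- fit_signature(feats, survival, sfs$selected,
                       ties = config$ties_method,
                       provenance = "discovered: FPR filter + CV forward selection")
  list(signature = sig, filter = filt, sfs = sfs)
}
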