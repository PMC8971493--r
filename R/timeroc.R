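#' Harrell's concordance index
#'
#' Proportion of admissible sample pairs in which the sample with the higher
#' predicted risk fails earlier. A pair is admissible when the member with the
#' earlier observed time had an event (or, at a tied time, exactly one member
#' had an event). Risk ties count 0.5.
#'
#' @param risk Numeric vector of predicted risk scores (higher = worse).
#' @inheritParams fit_cox
#' @return Concordance index in [0, 1].
#' @export
concordance_index <- function(risk, survival) {
  surv <- as_survival_data(survival)
  risk <- as.numeric(risk)
  if (length(risk) != nrow(surv)) {
    stop("`risk` length must match the number of samples", call. = FALSE)
  }
  if (length(risk) < 2L) stop("need at least two samples", call. = FALSE)
  t <- surv$time
  d <- surv$event
  # admissible (i, j): i fails first and is observed to fail
  adm <- outer(t, t, "<") & (d == 1L)
  adm <- adm | (outer(t, t, "==") & outer(d == 1L, d == 0L, "&"))
  n_pairs <- sum(adm)
  if (n_pairs == 0L) {
    stop("concordance undefined: no admissible pairs", call. = FALSE)
  }
  conc <- sum(adm & outer(risk, risk, ">")) +
    0.5 * sum(adm & outer(risk, risk, "=="))
  conc / n_pairs
}

#' IPCW time-dependent ROC AUC (cumulative cases / dynamic controls)
#'
#' Area under the time-dependent ROC curve at a fixed horizon, with inverse
#' probability of censoring weighting. Cases are samples with an observed
#' event at or before the horizon; controls are samples followed beyond it.
#' Case weights are `1 / G(T-)` where `G` is the Kaplan-Meier estimate of the
#' censoring survival function evaluated just before the case's event time;
#' control weights are `1 / G(horizon)`. Marker ties contribute 0.5. Without
#' censoring all weights are equal and the estimate reduces to the
#' Mann-Whitney AUC of cases versus controls.
#'
#' @param marker Numeric vector of marker values (higher = predicted earlier
#'   failure).
#' @inheritParams fit_cox
#' @param horizon Evaluation time in months (the study horizon is 6 months).
#' @return Object of class `time_roc`: `horizon`, `auc`, `n_cases`,
#'   `n_controls`, `ci95` (`NULL` unless bootstrapped downstream).
#' @export
ipcw_auc <- function(marker, survival, horizon) {
  surv <- as_survival_data(survival)
  marker <- as.numeric(marker)
  if (length(marker) != nrow(surv)) {
    stop("`marker` length must match the number of samples", call. = FALSE)
  }
  stopifnot(is.numeric(horizon), length(horizon) == 1L, horizon > 0)
  case <- surv$time <= horizon & surv$event == 1L
  ctrl <- surv$time > horizon
  if (!any(case) || !any(ctrl)) {
    stop("horizon error: need at least one case (event <= horizon) and one ",
         "control (followed beyond horizon)", call. = FALSE)
  }
  # censoring-distribution KM: censorings become the events
  cens_km <- km_estimate(data.frame(time = surv$time, event = 1L - surv$event))
  w_case <- 1 / km_survival_at(cens_km, surv$time[case], left = TRUE)
  w_ctrl <- rep(1 / km_survival_at(cens_km, horizon), sum(ctrl))
  if (any(!is.finite(w_case)) || any(!is.finite(w_ctrl))) {
    stop("IPCW weights undefined: censoring survival reaches zero before ",
         "the horizon", call. = FALSE)
  }
  mc <- marker[case]
  mk <- marker[ctrl]
  gt <- outer(mc, mk, ">")
  eq <- outer(mc, mk, "==")
  ww <- outer(w_case, w_ctrl)
  auc <- sum(ww * (gt + 0.5 * eq)) / sum(ww)
  structure(list(horizon = horizon, auc = auc, n_cases = sum(case),
                 n_controls = sum(ctrl), ci95 = NULL),
            class = "time_roc")
}

#' @export
print.time_roc <- function(x, ...) {
  cat("Time-dependent ROC at ", x$horizon, " months: AUC = ",
      round(x$auc, 4), " (", x$n_cases, " cases, ", x$n_controls,
      " controls)\n", sep = "")
  if (!is.null(x$ci95)) {
    cat("  bootstrap 95% CI: [", round(x$ci95[1], 4), ", ",
        round(x$ci95[2], 4), "]\n", sep = "")
  }
  invisible(x)
}
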