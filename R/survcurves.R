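#' Kaplan-Meier product-limit estimate
#'
#' @inheritParams fit_cox
#' @return Object of class `km_curve`: `event_times` (sorted distinct times at
#'   which at least one event occurred), `survival` (step-function values),
#'   `at_risk` (risk-set size just before each event time), `n`, `n_events`.
#' @examples
#' km_estimate(data.frame(time = c(1, 2, 3), event = 1))
#' @export
km_estimate <- function(survival) {
  surv <- as_survival_data(survival)
  if (nrow(surv) < 1L) stop("at least one sample required", call. = FALSE)
  tt <- sort(unique(surv$time[surv$event == 1L]))
  if (length(tt) == 0L) {
    res <- list(event_times = numeric(0), survival = numeric(0),
                at_risk = integer(0), n = nrow(surv), n_events = 0L)
    return(structure(res, class = "km_curve"))
  }
  n_risk <- vapply(tt, function(t) sum(surv$time >= t), integer(1))
  d <- vapply(tt, function(t) sum(surv$time == t & surv$event == 1L),
              integer(1))
  s <- cumprod(1 - d / n_risk)
  structure(list(event_times = tt, survival = s, at_risk = n_risk,
                 n = nrow(surv), n_events = sum(surv$event)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, ", events =", x$n_events, "\n")
  if (length(x$event_times)) {
    print(utils::head(data.frame(time = x$event_times, at_risk = x$at_risk,
                                 survival = round(x$survival, 4)), 10))
    if (length(x$event_times) > 10) cat("...\n")
  }
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step-function evaluation; `left = TRUE` returns the left
#' limit S(t-), i.e. the value just before `t`.
#'
#' @param km A `km_curve`.
#' @param t Numeric vector of times.
#' @param left Use the left limit.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, t, left = FALSE) {
  if (length(km$event_times) == 0L) return(rep(1, length(t)))
  step <- stats::stepfun(km$event_times, c(1, km$survival), right = FALSE)
  if (left) {
    vapply(t, function(ti) {
      keep <- km$event_times < ti
      if (!any(keep)) 1 else km$survival[max(which(keep))]
    }, numeric(1))
  } else {
    step(t)
  }
}

#' Export a Kaplan-Meier curve as a data.frame
#'
#' @param km A `km_curve`.
#' @return data.frame with columns `time`, `survival`, `at_risk`.
#' @export
km_as_table <- function(km) {
  data.frame(time = km$event_times, survival = km$survival,
             at_risk = km$at_risk)
}

#' Log-rank test
#'
#' Standard (unweighted) log-rank comparison of two or more survival curves.
#' The two-sided p-value comes from the chi-square distribution with
#' (number of groups - 1) degrees of freedom. With two groups and Breslow tie
#' handling the statistic equals the Cox partial-likelihood score test on the
#' group indicator.
#'
#' @param groups Vector of group labels, one per sample (>= 2 non-empty
#'   groups).
#' @inheritParams fit_cox
#' @return Object of class `logrank_test`: `chi_square`, `df`, `p_value`,
#'   `observed`, `expected` (per group).
#' @export
logrank_test <- function(groups, survival) {
  surv <- as_survival_data(survival)
  groups <- as.factor(groups)
  if (length(groups) != nrow(surv)) {
    stop("`groups` length must match the number of samples", call. = FALSE)
  }
  groups <- droplevels(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("log-rank test requires at least two groups", call. = FALSE)
  require_events(surv)

  tt <- sort(unique(surv$time[surv$event == 1L]))
  obs <- exp_ <- stats::setNames(numeric(k), levels(groups))
  V <- matrix(0, k, k, dimnames = list(levels(groups), levels(groups)))
  for (t in tt) {
    at_risk <- surv$time >= t
    n <- sum(at_risk)
    nj <- vapply(levels(groups), function(g) sum(at_risk & groups == g),
                 numeric(1))
    is_d <- surv$time == t & surv$event == 1L
    d <- sum(is_d)
    dj <- vapply(levels(groups), function(g) sum(is_d & groups == g),
                 numeric(1))
    obs <- obs + dj
    exp_ <- exp_ + d * nj / n
    if (n > 1) {
      hyper <- d * (n - d) / (n - 1)
      V <- V + hyper * (diag(nj * n, k) - outer(nj, nj)) / n^2
    }
  }
  # drop one group: the O - E vector sums to zero
  idx <- seq_len(k - 1L)
  u <- (obs - exp_)[idx]
  chi <- drop(crossprod(u, solve(V[idx, idx, drop = FALSE], u)))
  structure(list(chi_square = chi, df = k - 1L,
                 p_value = stats::pchisq(chi, k - 1L, lower.tail = FALSE),
                 observed = obs, expected = exp_),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Log-rank test: chi-square =", signif(x$chi_square, 5),
      "on", x$df, "df, p =", signif(x$p_value, 4), "\n")
  print(data.frame(observed = x$observed, expected = round(x$expected, 2)))
  invisible(x)
}
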