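# Independent brute-force oracles. These are direct transcriptions of the
# defining formulas (naive loops, no shared code with the package internals)
# used to pin down expected values.

# Naive Cox log partial likelihood for a single covariate, vectorised over a
# beta grid. Risk sets and tie corrections are built by explicit loops.
oracle_cox_loglik <- function(beta_grid, x, time, event,
                              ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  ll <- numeric(length(beta_grid))
  for (bi in seq_along(beta_grid)) {
    beta <- beta_grid[bi]
    total <- 0
    for (t in sort(unique(time[event == 1]))) {
      D <- which(time == t & event == 1)        # tied events at t
      R <- which(time >= t)                     # risk set
      d <- length(D)
      sum_risk <- sum(exp(beta * x[R]))
      sum_tied <- sum(exp(beta * x[D]))
      total <- total + sum(beta * x[D])
      for (l in seq_len(d) - 1) {
        frac <- if (ties == "efron") l / d else 0
        total <- total - log(sum_risk - frac * sum_tied)
      }
    }
    ll[bi] <- total
  }
  ll
}

# Two-stage grid search maximiser of the naive partial likelihood.
oracle_cox_grid <- function(x, time, event, ties = "efron",
                            lo = -5, hi = 5) {
  coarse <- seq(lo, hi, by = 1e-2)
  b0 <- coarse[which.max(oracle_cox_loglik(coarse, x, time, event, ties))]
  fine <- seq(b0 - 2e-2, b0 + 2e-2, by = 1e-4)
  fine[which.max(oracle_cox_loglik(fine, x, time, event, ties))]
}

# Hand accumulation of the two-group log-rank statistic.
oracle_logrank_2g <- function(g, time, event) {
  g <- as.integer(as.factor(g))
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n - d) / (n - 1) * n1 * (n - n1) / n^2
  }
  list(o_minus_e = O - E, variance = V, chi_square = (O - E)^2 / V)
}

# Exhaustive-pair Harrell concordance.
oracle_concordance <- function(risk, time, event) {
  num <- den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    admissible <- (time[i] < time[j] && event[i] == 1) ||
      (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (!admissible) next
    den <- den + 1
    if (risk[i] > risk[j]) num <- num + 1
    else if (risk[i] == risk[j]) num <- num + 0.5
  }
  num / den
}

# Product-limit estimate of the censoring survival function by direct loops,
# evaluated with a left limit; then the IPCW AUC as an explicit weighted
# double sum.
oracle_ipcw_auc <- function(marker, time, event, horizon) {
  cens_times <- sort(unique(time[event == 0]))
  G <- function(t, left = FALSE) {
    s <- 1
    for (ct in cens_times) {
      if ((left && ct < t) || (!left && ct <= t)) {
        n_risk <- sum(time >= ct)
        d <- sum(time == ct & event == 0)
        s <- s * (1 - d / n_risk)
      }
    }
    s
  }
  cases <- which(time <= horizon & event == 1)
  ctrls <- which(time > horizon)
  num <- den <- 0
  for (i in cases) for (j in ctrls) {
    w <- (1 / G(time[i], left = TRUE)) * (1 / G(horizon))
    den <- den + w
    if (marker[i] > marker[j]) num <- num + w
    else if (marker[i] == marker[j]) num <- num + 0.5 * w
  }
  num / den
}

# Pearson / Yates chi-square from the defining formula.
oracle_chisq <- function(tab, yates) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  adj <- if (yates) pmin(abs(tab - E), 0.5) else 0
  chi <- sum((abs(tab - E) - adj)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(chi_square = chi, df = df,
       p_value = pchisq(chi, df, lower.tail = FALSE))
}

# Welch t statistic with Satterthwaite df from the defining formula.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

# Small random survival dataset generator for property loops. `untied` draws
# continuous times: the log-rank / Breslow-score identity holds exactly only
# there (with tied deaths the log-rank variance carries a multiplicity factor
# the score information does not).
random_surv_data <- function(n, tie_prob = 0.3, event_prob = 0.7,
                             untied = FALSE) {
  time <- if (!untied && runif(1) < tie_prob) {
    sample(1:4, n, replace = TRUE)  # force ties
  } else {
    rexp(n, 0.3)
  }
  data.frame(time = time, event = rbinom(n, 1, event_prob))
}
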