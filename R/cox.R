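#' Fit a Cox proportional hazards model
#'
#' Maximises the Cox partial likelihood by Newton-Raphson with step-halving,
#' using either the Efron (default) or Breslow approximation for tied event
#' times. Standard errors come from the inverse observed information at the
#' maximum; 95% confidence intervals are Wald intervals `exp(beta +/- 1.96 SE)`.
#'
#' Convergence is declared when the largest score component falls below
#' `1e-7` or the largest coefficient change falls below `1e-9`, within 100
#' iterations. A monotone partial likelihood (perfect separation of risk by a
#' covariate) is reported as an error rather than returning a diverging
#' coefficient.
#'
#' @param covariates Numeric matrix or data.frame, samples in rows and
#'   covariates in columns. No missing values, no constant columns.
#' @param survival A data.frame (or list) with `time` (months, non-negative)
#'   and `event` (1 = death observed, 0 = censored).
#' @param ties Tie-handling method, `"efron"` or `"breslow"`.
#' @return An object of class `cox_fit`: a list with `coefficients`,
#'   `standard_errors`, `hazard_ratios`, `ci95` (matrix with `lower`/`upper`),
#'   `wald_p`, `log_partial_likelihood`, `null_log_partial_likelihood`,
#'   `information`, `ties_method`, `converged`, `iterations`, `n`, `n_events`.
#' @examples
#' surv <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = 1)
#' x <- matrix(c(0, 0, 0, 1, 1, 1), dimnames = list(NULL, "group"))
#' fit_cox(x, surv)
#' @export
fit_cox <- function(covariates, survival, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- as_covariate_matrix(covariates)
  surv <- as_survival_data(survival)
  require_events(surv)
  if (nrow(x) != nrow(surv)) {
    stop("covariates and survival describe different numbers of samples",
         call. = FALSE)
  }
  rng <- vapply(seq_len(ncol(x)),
                function(j) max(x[, j]) - min(x[, j]), numeric(1))
  if (any(rng == 0)) {
    stop("degenerate covariate: column(s) ",
         paste(colnames(x)[rng == 0], collapse = ", "),
         " constant across samples", call. = FALSE)
  }

  pl <- cox_prepare(x, surv, ties)
  p <- ncol(x)
  beta <- rep(0, p)
  eval0 <- cox_eval(beta, pl)
  ll0 <- eval0$loglik
  ll <- ll0
  ev <- eval0
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(100L)) {
    step <- tryCatch(solve(ev$info, ev$score), error = function(e) NULL)
    if (is.null(step)) {
      stop("singular information matrix: covariates may be collinear",
           call. = FALSE)
    }
    # step-halving on partial-likelihood decrease
    halve <- 0L
    repeat {
      cand <- beta + step
      ev_new <- cox_eval(cand, pl)
      if (is.finite(ev_new$loglik) && ev_new$loglik >= ll - 1e-12) break
      step <- step / 2
      halve <- halve + 1L
      if (halve > 30L) break
    }
    delta <- max(abs(cand - beta))
    beta <- cand
    ll <- ev_new$loglik
    ev <- ev_new
    if (max(abs(ev$score)) < 1e-7 || delta < 1e-9) {
      converged <- TRUE
      break
    }
    if (max(abs(beta)) > 20) {
      stop("diverging coefficient (|beta| > 20): monotone partial ",
           "likelihood, a covariate perfectly separates risk", call. = FALSE)
    }
  }

  # A monotone likelihood lets the score vanish along a diverging ray, so a
  # separated fit can pass the score test above. Probe each coordinate whose
  # contribution to the linear-predictor spread is extreme: if doubling it
  # does not reduce the partial likelihood, the maximum is at infinity.
  big <- which(abs(beta) > 5 | abs(beta) * rng > 10)
  for (j in big) {
    probe <- beta
    probe[j] <- 2 * probe[j]
    if (cox_eval(probe, pl)$loglik >= ll - 1e-10) {
      nm <- colnames(x)[j]
      stop("monotone partial likelihood: covariate ",
           if (is.null(nm)) j else nm,
           " perfectly separates risk (coefficient diverges)", call. = FALSE)
    }
  }

  vcov <- solve(ev$info)
  se <- sqrt(diag(vcov))
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))
  names(beta) <- names(se) <- nm
  hr <- exp(beta)
  ci <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
  rownames(ci) <- nm
  wald_p <- 2 * stats::pnorm(-abs(beta / se))

  structure(list(
    coefficients = beta,
    standard_errors = se,
    hazard_ratios = hr,
    ci95 = ci,
    wald_p = wald_p,
    log_partial_likelihood = ll,
    null_log_partial_likelihood = ll0,
    information = ev$info,
    vcov = vcov,
    ties_method = ties,
    converged = converged,
    iterations = iter,
    n = nrow(x),
    n_events = sum(surv$event)
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional hazards fit (", x$ties_method, " ties), n = ", x$n,
      ", events = ", x$n_events, "\n", sep = "")
  tab <- data.frame(
    coef = x$coefficients,
    `HR` = x$hazard_ratios,
    `se` = x$standard_errors,
    `lower95` = x$ci95[, "lower"],
    `upper95` = x$ci95[, "upper"],
    `p` = x$wald_p
  )
  print(round(tab, 4))
  invisible(x)
}

#' Cox score test at beta = 0
#'
#' Evaluates the partial-likelihood score statistic `U' I^-1 U` at the null.
#' With a single two-level group indicator and Breslow tie handling this is
#' algebraically identical to the (unweighted) log-rank chi-square.
#'
#' @inheritParams fit_cox
#' @return List with `chi_square`, `df`, `p_value`.
#' @export
cox_score_test <- function(covariates, survival, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  x <- as_covariate_matrix(covariates)
  surv <- as_survival_data(survival)
  require_events(surv)
  pl <- cox_prepare(x, surv, ties)
  ev <- cox_eval(rep(0, ncol(x)), pl)
  chi <- drop(crossprod(ev$score, solve(ev$info, ev$score)))
  df <- ncol(x)
  list(chi_square = chi, df = df,
       p_value = stats::pchisq(chi, df, lower.tail = FALSE))
}

# ---- internal partial-likelihood machinery -------------------------------

# Pre-sorts the data and builds the tied-event index structures so that each
# Newton-Raphson iteration is a handful of vectorised cumulative sums.
cox_prepare <- function(x, surv, ties) {
  ord <- order(surv$time, -surv$event)  # events before censorings at ties
  x <- x[ord, , drop = FALSE]
  time <- surv$time[ord]
  event <- surv$event[ord]
  n <- length(time)
  p <- ncol(x)

  ev_idx <- which(event == 1L)
  ev_time <- time[ev_idx]
  grp <- match(ev_time, unique(ev_time))      # tied-event group per event
  d <- as.vector(table(grp))                  # ties per group
  # first sorted position whose time >= each group's event time:
  # reverse cumulative sums indexed here give the risk-set sums
  grp_start <- ev_idx[!duplicated(grp)]
  # Efron fraction l/d for each event within its group; Breslow uses 0
  l_within <- stats::ave(grp, grp, FUN = seq_along) - 1
  frac <- if (ties == "efron") l_within / d[grp] else rep(0, length(grp))

  # precompute cross-product columns for the information matrix
  pairs <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  list(x = x, time = time, event = event, n = n, p = p,
       ev_idx = ev_idx, grp = grp, grp_start = grp_start, frac = frac,
       no_ties = max(d) == 1L, pairs = pairs)
}

rcumsum <- function(v) rev(cumsum(rev(v)))
# Column-wise reverse cumulative sums without apply(): one cumsum over the
# flattened matrix, corrected by per-column offsets.
rcumsum_mat <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  if (k == 1L) return(matrix(rcumsum(m[, 1L]), n))
  rv <- m[n:1L, , drop = FALSE]
  v <- cumsum(rv)
  off <- c(0, v[seq.int(n, n * (k - 1L), by = n)])
  matrix(v - rep(off, each = n), n, k)[n:1L, , drop = FALSE]
}

# Log partial likelihood, score and observed information at beta.
cox_eval <- function(beta, pl) {
  x <- pl$x
  p <- pl$p
  eta <- drop(x %*% beta)
  eta <- eta - max(eta)  # guard exp overflow; cancels in all ratios
  w <- exp(eta)
  wx <- x * w
  xx <- x[, pl$pairs[, 1L], drop = FALSE] * x[, pl$pairs[, 2L], drop = FALSE]
  wxx <- xx * w

  gs <- pl$grp_start
  S0 <- rcumsum(w)[gs][pl$grp]
  S1 <- rcumsum_mat(wx)[gs, , drop = FALSE][pl$grp, , drop = FALSE]
  S2 <- rcumsum_mat(wxx)[gs, , drop = FALSE][pl$grp, , drop = FALSE]

  ev <- pl$ev_idx
  if (pl$no_ties) {
    # untied event times: Efron and Breslow coincide, no adjustment terms
    d0 <- S0
    d1 <- S1
    d2 <- S2
  } else {
    # tied-event sums per group, expanded back to one row per event
    t0 <- rowsum(w[ev], pl$grp)[pl$grp, 1L]
    t1 <- rowsum(wx[ev, , drop = FALSE], pl$grp)[pl$grp, , drop = FALSE]
    t2 <- rowsum(wxx[ev, , drop = FALSE], pl$grp)[pl$grp, , drop = FALSE]
    f <- pl$frac
    d0 <- S0 - f * t0
    d1 <- S1 - f * t1
    d2 <- S2 - f * t2
  }

  loglik <- sum(eta[ev]) - sum(log(d0))
  m1 <- d1 / d0
  score <- colSums(x[ev, , drop = FALSE]) - colSums(m1)

  # information: sum over events of d2/d0 - m1 m1'
  iflat <- colSums(d2 / d0) - colSums(m1[, pl$pairs[, 1L], drop = FALSE] *
                                        m1[, pl$pairs[, 2L], drop = FALSE])
  info <- matrix(0, p, p)
  info[cbind(pl$pairs[, 1L], pl$pairs[, 2L])] <- iflat
  info[cbind(pl$pairs[, 2L], pl$pairs[, 1L])] <- iflat

  list(loglik = loglik, score = score, info = info)
}
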