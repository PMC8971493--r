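#' Select housekeeping miRNAs by low variance
#'
#' Among features whose median RPM is at least `floor`, returns the `k`
#' features with the smallest variance of `log2(RPM + 1)` across samples —
#' the NGS-based definition of stable normalisation assays.
#'
#' @param expression RPM matrix, samples x miRNAs.
#' @param k Number of housekeepers.
#' @param floor Minimum median RPM for eligibility.
#' @return Character vector of `k` feature names (most stable first).
#' @export
select_housekeepers <- function(expression, k = 3L, floor = 50) {
  x <- as.matrix(expression)
  med <- apply(x, 2L, stats::median)
  eligible <- colnames(x)[med >= floor]
  if (length(eligible) < k) {
    stop("eligibility error: only ", length(eligible),
         " feature(s) reach median RPM >= ", floor, ", need ", k,
         call. = FALSE)
  }
  v <- apply(log2(x[, eligible, drop = FALSE] + 1), 2L, stats::var)
  eligible[order(v)][seq_len(k)]
}

#' Delta-Ct normalisation
#'
#' Averages technical replicates per sample x assay, then subtracts the mean
#' housekeeper Ct from each target Ct: `dCt = Ct_target -
#' mean(Ct_housekeepers)`. Lower dCt means higher expression. The result is
#' invariant to plate-wide Ct shifts within a sample.
#'
#' @param ct Long-format Ct table (`sample`, `assay`, `replicate`, `ct`),
#'   e.g. from [simulate_qpcr()].
#' @param housekeepers Housekeeper assay names; every sample must carry
#'   measurements for all of them.
#' @param targets Target assay names; defaults to all non-housekeeper assays.
#' @return Matrix of dCt values, samples x targets.
#' @export
delta_ct <- function(ct, housekeepers, targets = NULL) {
  stopifnot(all(c("sample", "assay", "ct") %in% names(ct)))
  mean_ct <- tapply(ct$ct, list(ct$sample, ct$assay), mean)
  missing_hk <- setdiff(housekeepers, colnames(mean_ct))
  if (length(missing_hk) || anyNA(mean_ct[, housekeepers])) {
    stop("incompleteness error: housekeeper Ct missing for some sample",
         call. = FALSE)
  }
  if (is.null(targets)) targets <- setdiff(colnames(mean_ct), housekeepers)
  hk <- rowMeans(mean_ct[, housekeepers, drop = FALSE])
  dct <- mean_ct[, targets, drop = FALSE] - hk
  dct
}

#' Delta-delta-Ct fold change between risk groups
#'
#' `ddCt = mean dCt(high) - mean dCt(low)`; the fold change of the high- vs
#' low-risk group is `2^(-ddCt)` (fold change > 1 means higher expression in
#' the high-risk group). Group means are compared by a two-sided Welch
#' t-test on the dCt values; with fewer than 2 samples in a group the fold
#' change is still returned but the test is NA.
#'
#' @param dct Per-sample dCt values for one target (numeric vector).
#' @param groups Factor with levels `low`/`high` (or coercible), one per
#'   sample.
#' @return List: `fold_change`, `ddct`, `t`, `df`, `p_value`, `n_low`,
#'   `n_high`.
#' @export
fold_change_ddct <- function(dct, groups) {
  groups <- as.factor(groups)
  if (!all(levels(droplevels(groups)) %in% c("low", "high"))) {
    groups <- factor(ifelse(groups == levels(groups)[1L], "low", "high"),
                     levels = c("low", "high"))
  }
  lo <- dct[groups == "low"]
  hi <- dct[groups == "high"]
  if (!length(lo) || !length(hi)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ddct <- mean(hi) - mean(lo)
  fc <- 2^(-ddct)
  if (length(lo) >= 2L && length(hi) >= 2L) {
    ht <- welch_ttest(hi, lo)
    list(fold_change = fc, ddct = ddct, t = ht$t, df = ht$df,
         p_value = ht$p_value, n_low = length(lo), n_high = length(hi))
  } else {
    list(fold_change = fc, ddct = ddct, t = NA_real_, df = NA_real_,
         p_value = NA_real_, n_low = length(lo), n_high = length(hi))
  }
}

#' qPCR concordance report across targets
#'
#' Convenience wrapper: dCt per target, then group fold change and Welch
#' test per target.
#'
#' @inheritParams delta_ct
#' @param groups Risk-group factor, one per sample (rows of the dCt matrix).
#' @return data.frame: one row per target with `fold_change`, `ddct`, `t`,
#'   `p_value`, group sizes.
#' @export
qpcr_group_report <- function(ct, housekeepers, groups, targets = NULL) {
  dct <- delta_ct(ct, housekeepers, targets)
  rows <- lapply(colnames(dct), function(tg) {
    res <- fold_change_ddct(dct[, tg], groups)
    data.frame(target = tg, fold_change = res$fold_change, ddct = res$ddct,
               t = res$t, p_value = res$p_value, n_low = res$n_low,
               n_high = res$n_high)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Blocking efficiency of high-abundance miRNA suppression
#'
#' Compares paired unblocked/blocked libraries: the per-sample proportion of
#' raw reads mapping to the blocking targets in each condition, the percent
#' reduction of the pooled target fraction
#' (`100 * (1 - blocked / unblocked)`), and the Pearson correlation of mean
#' `log2(RPM)` across miRNAs detected (mean RPM > 0) in both conditions with
#' the targets excluded.
#'
#' @param unblocked,blocked Raw read-count matrices (samples x miRNAs) from
#'   the two library preparations of the same samples, rows aligned.
#' @param targets Names of the blocked miRNAs (present in the unblocked
#'   panel).
#' @return List of class `blocking_comparison`: `target_fraction_unblocked`,
#'   `target_fraction_blocked` (per-sample vectors), `pooled_unblocked`,
#'   `pooled_blocked`, `reduction_pct`, `pearson_r`, `n_shared_features`.
#' @export
blocking_efficiency <- function(unblocked, blocked, targets) {
  u <- as.matrix(unblocked)
  b <- as.matrix(blocked)
  if (nrow(u) != nrow(b) ||
      !identical(rownames(u), rownames(b))) {
    stop("pairing error: unblocked and blocked must hold the same samples ",
         "in the same order", call. = FALSE)
  }
  missing <- setdiff(targets, colnames(u))
  if (length(missing)) {
    stop("feature error: target(s) absent from unblocked panel: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tu <- intersect(targets, colnames(u))
  tb <- intersect(targets, colnames(b))
  frac_u <- rowSums(u[, tu, drop = FALSE]) / rowSums(u)
  frac_b <- if (length(tb)) rowSums(b[, tb, drop = FALSE]) / rowSums(b) else
    rep(0, nrow(b))
  pooled_u <- sum(u[, tu, drop = FALSE]) / sum(u)
  pooled_b <- if (length(tb)) sum(b[, tb, drop = FALSE]) / sum(b) else 0
  reduction <- 100 * (1 - pooled_b / pooled_u)

  # mean log2 RPM correlation over shared non-target features
  rpm_u <- u / rowSums(u) * 1e6
  rpm_b <- b / rowSums(b) * 1e6
  shared <- setdiff(intersect(colnames(u), colnames(b)), targets)
  mu <- colMeans(rpm_u[, shared, drop = FALSE])
  mb <- colMeans(rpm_b[, shared, drop = FALSE])
  keep <- mu > 0 & mb > 0
  r <- stats::cor(log2(mu[keep]), log2(mb[keep]))
  structure(list(target_fraction_unblocked = frac_u,
                 target_fraction_blocked = frac_b,
                 pooled_unblocked = pooled_u, pooled_blocked = pooled_b,
                 reduction_pct = reduction, pearson_r = r,
                 n_shared_features = sum(keep)),
            class = "blocking_comparison")
}

#' @export
print.blocking_comparison <- function(x, ...) {
  cat("Blocking efficiency: pooled target fraction ",
      signif(x$pooled_unblocked, 4), " (unblocked) -> ",
      signif(x$pooled_blocked, 4), " (blocked); reduction ",
      round(x$reduction_pct, 2), "%\n", sep = "")
  cat("off-target mean log2 RPM Pearson r = ", round(x$pearson_r, 4),
      " over ", x$n_shared_features, " shared miRNAs\n", sep = "")
  invisible(x)
}
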