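test_that("group comparison is symmetric and null on duplicated data", {
  surv1 <- data.frame(time = c(2, 3, 5, 7, 11), event = c(1, 1, 0, 1, 1))
  surv <- rbind(surv1, surv1)
  res <- compare_groups_survival(rep(c("low", "high"), each = 5), surv)
  expect_equal(res$hr, 1)
  expect_equal(res$logrank_p, 1)
  set.seed(61)
  surv2 <- data.frame(time = rexp(80, 0.2), event = rbinom(80, 1, 0.8))
  g <- factor(rep(c("low", "high"), 40), levels = c("low", "high"))
  a <- compare_groups_survival(g, surv2)
  b <- compare_groups_survival(factor(ifelse(g == "low", "high", "low"),
                                      levels = c("low", "high")), surv2)
  expect_lt(abs(a$hr - 1 / b$hr), 1e-9)
  expect_error(compare_groups_survival(rep("low", 80), surv2), "grouping")
})

test_that("a planted two-fold hazard is recovered by the group HR", {
  set.seed(67)
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    n <- 400
    g <- rep(c("low", "high"), each = n / 2)
    rate <- ifelse(g == "high", 0.2, 0.1)
    surv <- data.frame(time = rexp(n, rate), event = 1L)
    res <- compare_groups_survival(factor(g, levels = c("low", "high")), surv)
    se <- res$cox_fit$standard_errors[[1]]
    if (abs(log(res$hr) - log(2)) <= 2 * se) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("PD-L1 marker codes the trichotomy ordinally", {
  expect_equal(pd_l1_marker(c("<1", "1-49", ">=50")), c(0L, 1L, 2L))
  expect_equal(pd_l1_marker(c("≥50", "1–49")), c(2L, 1L))
  expect_error(pd_l1_marker("50+"), "vocabulary error")
})

test_that("covariate table applies the fixed dichotomisations", {
  cfg <- sim_config(n_samples = 400L, n_mirnas = 30L, seed = 71L)
  co <- simulate_cohort(cfg)
  risk <- stratify(co$ground_truth$true_linear_predictor,
                   median(co$ground_truth$true_linear_predictor))
  uni <- cox_covariate_table(co$clinical, risk, co$survival,
                             mode = "univariable")
  expect_true("miRisk (high vs low)" %in% uni$covariate)
  est <- !is.na(uni$hr)
  expect_gt(sum(est), 8L)
  expect_true(all(uni$hr[est] > 0))
  expect_true(all(uni$ci_lower[est] <= uni$hr[est] &
                    uni$hr[est] <= uni$ci_upper[est]))
  # univariable mode on one covariate equals a direct fit_cox
  direct <- fit_cox(matrix(as.numeric(co$clinical$age > 75),
                           dimnames = list(NULL, "age75")), co$survival)
  row <- uni[uni$covariate == "Age (>75 years)", ]
  expect_equal(row$hr, unname(direct$hazard_ratios[1]))
  expect_equal(row$p_value, unname(direct$wald_p[1]))
  multi <- cox_covariate_table(co$clinical, risk, co$survival,
                               mode = "multivariable")
  expect_equal(nrow(multi), nrow(uni))
  expect_equal(length(unique(multi$n_used)), 1L)
})

test_that("duplicated covariates are rejected as collinear in multivariable mode", {
  set.seed(73)
  surv <- data.frame(time = rexp(60, 0.2), event = rbinom(60, 1, 0.8))
  x <- rbinom(60, 1, 0.5)
  expect_error(fit_cox(cbind(a = x, b = x), surv), "singular|collinear")
})

test_that("bootstrap AUC difference honours its identities", {
  set.seed(79)
  n <- 120
  time <- rexp(n, 0.15)
  surv <- data.frame(time = time, event = rbinom(n, 1, 0.8))
  m <- rnorm(n)
  horizon <- median(time)
  same <- bootstrap_auc_difference(m, m, surv, horizon, n_boot = 50,
                                   seed = 3)
  expect_equal(same$delta, 0)
  expect_equal(same$delta_ci95, c(0, 0))
  mono <- bootstrap_auc_difference(m, exp(m) + 5, surv, horizon,
                                   n_boot = 50, seed = 3)
  expect_equal(mono$delta, 0)
  # seed determinism; point delta independent of n_boot
  m2 <- rnorm(n)
  a <- bootstrap_auc_difference(m, m2, surv, horizon, n_boot = 30, seed = 7)
  b <- bootstrap_auc_difference(m, m2, surv, horizon, n_boot = 30, seed = 7)
  expect_identical(a$delta_ci95, b$delta_ci95)
  c2 <- bootstrap_auc_difference(m, m2, surv, horizon, n_boot = 60, seed = 7)
  expect_identical(a$delta, c2$delta)
  expect_error(bootstrap_auc_difference(m, m[-1], surv, horizon),
               "input error")
})

test_that("an informative marker beats noise with a CI excluding zero", {
  set.seed(83)
  wins <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    n <- 300
    lp <- rnorm(n)
    time <- rexp(n, 0.1 * exp(1.2 * lp))
    surv <- data.frame(time = time, event = 1L)
    res <- bootstrap_auc_difference(lp, rnorm(n), surv,
                                    horizon = median(time), n_boot = 200,
                                    seed = r)
    if (res$delta_ci95[1] > 0) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.9)
})

test_that("combined model adds PD-L1 and collapses to the miRNA score at weight zero", {
  cfg <- sim_config(n_samples = 250L, n_mirnas = 30L, seed = 89L)
  co <- simulate_cohort(cfg, clinical_association = 0.6)
  feats <- transform_expression(co$expression)
  pdl1 <- pd_l1_marker(co$clinical)
  comb <- combined_model(feats, pdl1, co$survival,
                         signature_features = cfg$planted_features)
  expect_true("PD-L1" %in% comb$features$mirna)
  expect_equal(nrow(comb$features), 6L)
  # forcing the PD-L1 weight to zero reproduces the miRNA-only predictor
  w <- comb$features$weight
  names(w) <- comb$features$mirna
  w["PD-L1"] <- 0
  lp_forced <- drop(cbind(feats[, cfg$planted_features], pdl1) %*% w)
  lp_mirna <- drop(feats[, cfg$planted_features] %*%
                     w[cfg$planted_features])
  expect_equal(lp_forced, lp_mirna)
})

test_that("permutation importance isolates informative features", {
  set.seed(97)
  n <- 300
  feats <- cbind(signal = rnorm(n), noise = rnorm(n))
  time <- rexp(n, 0.1 * exp(1.5 * feats[, "signal"]))
  surv <- data.frame(time = time, event = 1L)
  scorer <- function(x) x[, "signal"] + 0 * x[, "noise"]
  imp <- permutation_importance(scorer, feats, surv, n_repeats = 20,
                                seed = 5)
  c_full <- concordance_index(scorer(feats), surv)
  expect_lt(abs(imp[["noise"]]), 0.02)       # zero-weight feature
  expect_lt(abs(imp[["signal"]] - (c_full - 0.5)), 0.03)  # sole informative
  expect_gt(imp[["signal"]], imp[["noise"]])
})

test_that("chi-square and Welch wrappers match formula oracles", {
  set.seed(103)
  for (r in 1:30) {
    dims <- sample(2:4, 2, replace = TRUE)
    tab <- matrix(rpois(prod(dims), 20) + 1, dims[1], dims[2])
    res <- chisq_contingency(tab)
    ora <- oracle_chisq(tab, yates = all(dims == 2))
    expect_lt(abs(res$chi_square - ora$chi_square), 1e-12)
    expect_lt(abs(res$p_value - ora$p_value), 1e-12)
  }
  for (r in 1:20) {
    a <- rnorm(10)
    b <- rnorm(12, 0.3)
    res <- welch_ttest(a, b)
    ora <- oracle_welch(a, b)
    expect_lt(abs(res$t - ora$t), 1e-12)
    expect_lt(abs(res$df - ora$df), 1e-12)
    expect_lt(abs(res$p_value - ora$p_value), 1e-12)
  }
  expect_equal(welch_ttest(c(1, 1), c(1, 1))$p_value, 1)
  sym <- chisq_contingency(matrix(c(10, 10, 10, 10), 2))
  expect_equal(sym$chi_square, 0)
  expect_equal(sym$p_value, 1)
  expect_error(chisq_contingency(matrix(c(0, 0, 5, 5), 2)), "degenerate")
})

test_that("cohort self-comparison is null and NA rows are dropped per variable", {
  cfg <- sim_config(n_samples = 150L, n_mirnas = 20L, seed = 107L)
  co <- simulate_cohort(cfg)
  res <- cohort_characteristics(co$clinical, co$clinical)
  expect_true(all(res$p_value[res$test == "chisq"] == 1))
  clin_na <- co$clinical
  clin_na$smoking[1:10] <- NA
  res2 <- cohort_characteristics(clin_na, co$clinical)
  expect_true(is.finite(res2$p_full[res2$variable == "smoking"]))
  expect_error(cohort_characteristics(co$clinical[0, ], co$clinical),
               "input error")
})
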