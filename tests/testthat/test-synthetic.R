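cfg_small <- function(seed = 5L, ...) {
  sim_config(n_samples = 40L, n_mirnas = 120L,
             planted_features = c("miR-2115-3p", "miR-224-5p"),
             planted_weights = c(0.8, 0.8), seed = seed, ...)
}

test_that("expression rows close to one million RPM with the dominant mass planted", {
  cfg <- cfg_small()
  x <- simulate_expression(cfg)
  expect_equal(dim(x), c(40L, 120L))
  expect_true(all(abs(rowSums(x) - 1e6) < 0.5))
  dom <- rowSums(x[, 1:3])
  expect_true(all(abs(dom - 5e5) < 0.5))  # ~50% of reads on 3 features
  expect_true(all(x >= 0))
  expect_true(all(cfg$planted_features %in% colnames(x)))
})

test_that("dominant_fraction 0 removes the dominance structure", {
  cfg <- cfg_small(dominant_fraction = 0)
  x <- simulate_expression(cfg)
  expect_true(all(abs(rowSums(x) - 1e6) < 0.5))
  # dominant columns carry an unremarkable share of the mass
  expect_lt(mean(rowSums(x[, 1:3]) / 1e6), 0.3)
})

test_that("identical seeds give bit-identical cohorts, different seeds differ", {
  a <- simulate_cohort(cfg_small())
  b <- simulate_cohort(cfg_small())
  expect_identical(a$expression, b$expression)
  expect_identical(a$survival, b$survival)
  expect_identical(a$clinical, b$clinical)
  c2 <- simulate_cohort(cfg_small(seed = 6L))
  expect_false(identical(a$expression, c2$expression))
})

test_that("ground truth records the exact planted linear predictor", {
  co <- simulate_cohort(cfg_small())
  lp <- drop(log1p(co$expression[, co$config$planted_features]) %*%
               co$config$planted_weights)
  expect_identical(co$ground_truth$true_linear_predictor, unname(lp))
})

test_that("infinite accrual removes censoring; null weights give exponential times", {
  cfg <- cfg_small(accrual_months = Inf)
  x <- simulate_expression(cfg)
  ss <- simulate_survival(x, cfg)
  expect_true(all(ss$survival$event == 1L))
  # null planted weights: times are iid exponential(baseline)
  cfg0 <- sim_config(n_samples = 400L, n_mirnas = 50L,
                     planted_features = "miR-2115-3p", planted_weights = 0,
                     baseline_hazard = 0.1, accrual_months = Inf, seed = 8L)
  ss0 <- simulate_survival(simulate_expression(cfg0), cfg0)
  expect_gt(ks.test(ss0$survival$time, "pexp", 0.1)$p.value, 0.01)
  fit <- fit_cox(cbind(x = log1p(simulate_expression(cfg0)[, "miR-2115-3p"])),
                 ss0$survival)
  expect_lt(abs(fit$coefficients[[1]]), 2.5 * fit$standard_errors[[1]])
})

test_that("planted single coefficient is recovered within 2 SE in most replicates", {
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_samples = 500L, n_mirnas = 30L,
                      planted_features = "miR-2115-3p",
                      planted_weights = 0.8, seed = 100L + r)
    x <- simulate_expression(cfg)
    ss <- simulate_survival(x, cfg)
    fit <- fit_cox(cbind(m = log1p(x[, "miR-2115-3p"])), ss$survival)
    if (abs(fit$coefficients[[1]] - 0.8) <= 2 * fit$standard_errors[[1]]) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("unknown planted features and bad configs are rejected", {
  cfg <- cfg_small()
  x <- simulate_expression(cfg)
  bad <- cfg
  bad$planted_features <- "miR-not-there"
  expect_error(simulate_survival(x, bad), "feature error")
  expect_error(sim_config(n_mirnas = 0), "configuration error")
  expect_error(sim_config(n_dominant = 10, n_mirnas = 10), "configuration")
  expect_error(sim_config(dominant_fraction = 1), "configuration")
})

test_that("clinical covariates honour marginal frequencies and independence", {
  cfg <- sim_config(n_samples = 3000L, n_mirnas = 20L,
                    planted_features = "miR-2115-3p", planted_weights = 0.8,
                    seed = 12L)
  co <- simulate_cohort(cfg)
  clin <- co$clinical
  expect_equal(nrow(clin), 3000L)
  expect_false(anyNA(clin))
  # Table-1-like marginal: PD-L1 >= 50% in about 70.8% of samples
  expect_lt(abs(mean(clin$pd_l1_category == ">=50") - 68 / 96), 0.03)
  expect_true(all(clin$age > 0))
  # association = 0: PD-L1 independent of the planted predictor
  lp <- co$ground_truth$true_linear_predictor
  expect_gt(cor.test(lp, pd_l1_marker(clin))$p.value, 0.001)
  # positive association ties high-risk categories to high lp
  clin2 <- simulate_clinical(co$survival, cfg, association = 0.7,
                             ground_truth = co$ground_truth)
  expect_lt(cor(lp, pd_l1_marker(clin2)), -0.3)  # high TPS = low risk
})

test_that("cell atlas has planted exclusivity and a complete metadata grid", {
  cfg <- cfg_small()
  atl <- simulate_cell_atlas(cfg, n_donors = 12L, n_exclusive = 30L)
  expect_equal(dim(atl$atlas), c(120L, 10L, 12L))
  expect_equal(nrow(atl$metadata), 120L)  # 12 donors x 10 cell types
  expect_true(all(atl$atlas >= 0))
  for (m in names(atl$exclusive_truth)[1:5]) {
    other <- setdiff(blood_cell_types(), atl$exclusive_truth[[m]])
    expect_true(all(atl$atlas[m, other, ] == 0))
    expect_true(all(atl$atlas[m, atl$exclusive_truth[[m]], ] > 0))
  }
})

test_that("qPCR simulation is deterministic, triplicate, and maps expression", {
  cfg <- cfg_small()
  x <- simulate_expression(cfg)
  ct <- simulate_qpcr(x, targets = "miR-2115-3p", housekeepers = "miR-16-5p",
                      config = cfg, noise_sd = 0)
  expect_equal(nrow(ct), 40L * 2L * 3L)
  expect_identical(ct,
                   simulate_qpcr(x, "miR-2115-3p", "miR-16-5p", cfg,
                                 noise_sd = 0))
  # zero noise, slope 1: Ct differences reproduce log2 expression ratios
  one <- ct[ct$sample == "S001" & ct$replicate == 1L, ]
  dct <- one$ct[one$assay == "miR-2115-3p"] - one$ct[one$assay == "miR-16-5p"]
  expect_equal(dct, log2(x["S001", "miR-16-5p"] + 1) -
                 log2(x["S001", "miR-2115-3p"] + 1))
  expect_error(simulate_qpcr(x, "miR-2115-3p", "miR-2115-3p", cfg),
               "configuration error")
})
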