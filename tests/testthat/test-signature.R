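test_that("expression transform is the natural log of RPM plus one", {
  x <- matrix(c(0, exp(1) - 1, 10, 999), 2,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  tx <- transform_expression(x)
  expect_equal(dim(tx), dim(x))
  expect_equal(tx[1, "a"], 0)
  expect_equal(tx[2, "a"], 1)
  expect_equal(tx[2, "b"], log(1000))
  expect_error(transform_expression(matrix(-1)), "domain error")
})

test_that("the frozen miRisk score evaluates its published formula", {
  sig <- mirisk_signature()
  expect_equal(sig$cutpoint, 5.61)
  expect_equal(sig$features$weight, c(1.870, 0.907, 0.495, 1.309, 1.159))
  zero <- setNames(rep(0, 5), sig$features$mirna)
  expect_equal(mirisk_score(zero), 0)
  unit <- setNames(rep(exp(1) - 1, 5), sig$features$mirna)
  expect_equal(mirisk_score(unit), 5.740)
  solo <- setNames(c(exp(2) - 1, 0, 0, 0, 0), sig$features$mirna)
  expect_equal(mirisk_score(solo), 2 * 1.870)
  # additive and order-invariant
  m <- rbind(a = c(10, 20, 30, 40, 50))
  colnames(m) <- sig$features$mirna
  shuffled <- m[, c(3, 1, 5, 2, 4), drop = FALSE]
  expect_equal(mirisk_score(m), mirisk_score(shuffled))
  expect_error(mirisk_score(m[, -2, drop = FALSE]), "miR-218-5p")
})

test_that("signature JSON round-trips exactly", {
  sig <- mirisk_signature()
  path <- withr::local_tempfile(fileext = ".json")
  write_signature_json(sig, path)
  back <- read_signature_json(path)
  expect_equal(back$features, sig$features)
  expect_equal(back$cutpoint, sig$cutpoint)
})

test_that("stratification uses a strict cutpoint with the median sample low", {
  lab <- stratify(c(5.60, 5.61, 5.62), 5.61)
  expect_equal(as.character(lab), c("low", "low", "high"))
  sc <- c(1, 2, 3, 4, 5)
  lab2 <- stratify(sc, median(sc))
  expect_equal(as.vector(table(lab2)), c(3L, 2L))  # median sample is low
  expect_true(all(stratify(sc, -Inf) == "high"))
})

test_that("univariable filter calibrates to its false positive rate under the null", {
  set.seed(41)
  retained <- 0L
  total <- 0L
  for (r in 1:8) {
    n <- 120
    m <- 400
    feats <- matrix(rnorm(n * m), n, dimnames = list(NULL, paste0("f", 1:m)))
    surv <- data.frame(time = rexp(n, 0.1), event = rbinom(n, 1, 0.7))
    res <- univariable_cox_filter(feats, surv, alpha = 0.05)
    retained <- retained + length(res$selected)
    total <- total + m - length(res$dropped)
  }
  # binomial 3-SD band around alpha * m over the pooled replicates
  band <- 3 * sqrt(total * 0.05 * 0.95)
  expect_lt(abs(retained - 0.05 * total), band + 0.01 * total)
})

test_that("filter retains a strongly planted feature and honours alpha = 1", {
  set.seed(43)
  hits <- 0L
  for (r in 1:10) {
    cfg <- sim_config(n_samples = 300L, n_mirnas = 40L,
                      planted_features = "miR-2115-3p", planted_weights = 1,
                      seed = 200L + r)
    x <- simulate_expression(cfg)
    ss <- simulate_survival(x, cfg)
    res <- univariable_cox_filter(log1p(x), ss$survival, alpha = 0.05)
    if ("miR-2115-3p" %in% res$selected) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
  res_all <- univariable_cox_filter(log1p(x), ss$survival, alpha = 1)
  expect_equal(sort(res_all$selected),
               sort(setdiff(colnames(x), res_all$dropped)))
})

test_that("forward selection ranks the informative feature first", {
  # the CV objective must find the signal before any noise feature and keep
  # it in the final set; the chosen size itself can wander upward because
  # chance improvements from noise additions are only penalised by
  # tie-breaking (see the methods vignette)
  set.seed(47)
  first <- kept <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    n <- 200
    feats <- cbind(signal = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                   n3 = rnorm(n))
    time <- rexp(n, 0.1 * exp(1.0 * feats[, "signal"]))
    surv <- data.frame(time = time, event = 1L)
    sel <- sequential_forward_selection(
      feats, surv, selection_config(k_grid = 1:3, cv_seed = r))
    if (identical(sel$path[1], "signal")) first <- first + 1L
    if ("signal" %in% sel$selected) kept <- kept + 1L
  }
  expect_equal(first, n_rep)
  expect_equal(kept, n_rep)
})

test_that("discovery is idempotent for a fixed seed and fits the planted weights", {
  cfg <- sim_config(n_samples = 250L, n_mirnas = 150L, seed = 51L)
  co <- simulate_cohort(cfg)
  sc <- selection_config(k_grid = 1:5, cv_seed = 9L)
  d1 <- discover_signature(co$expression, co$survival, sc)
  d2 <- discover_signature(co$expression, co$survival, sc)
  expect_identical(d1$signature$features, d2$signature$features)
  expect_identical(d1$signature$cutpoint, d2$signature$cutpoint)
  # single selected feature: weight equals the univariable Cox coefficient
  feats <- transform_expression(co$expression)
  one <- fit_signature(feats, co$survival, d1$sfs$selected[1])
  uni <- fit_cox(feats[, d1$sfs$selected[1], drop = FALSE], co$survival)
  expect_equal(one$features$weight, unname(uni$coefficients))
  # cutpoint is the median training score: near-even split
  scores <- signature_score(d1$signature, co$expression)
  lab <- stratify(scores, d1$signature$cutpoint)
  expect_lte(abs(diff(as.vector(table(lab)))), 1L)
})

test_that("signature recovery: planted weights are within two standard errors", {
  cfg <- sim_config(n_samples = 400L, n_mirnas = 60L, seed = 53L)
  co <- simulate_cohort(cfg)
  feats <- transform_expression(co$expression)
  sig <- fit_signature(feats, co$survival, cfg$planted_features)
  dev <- abs(sig$features$weight - cfg$planted_weights)
  expect_true(all(dev <= 2 * sig$fit$standard_errors + 1e-9))
})
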