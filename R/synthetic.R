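#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every knob of the synthetic whole-blood miRNA cohort:
#' an RPM expression matrix dominated by a few erythroid-like features,
#' exponential survival times driven by a planted linear predictor on
#' log-transformed expression, uniform administrative censoring, Table-1-like
#' clinical covariates, a sorted-cell atlas, and qPCR Ct values.
#'
#' @param n_samples Number of patients.
#' @param n_mirnas Number of miRNA features.
#' @param n_dominant Number of dominant high-abundance (erythroid-like)
#'   features; whole-blood libraries concentrate roughly half of all reads on
#'   miR-486-5p, miR-451a and miR-16-5p, which these emulate.
#' @param dominant_fraction Fraction of each sample's total RPM mass carried
#'   jointly by the dominant features (0 disables the dominance structure).
#' @param planted_features Names of the features that drive survival.
#' @param planted_weights Log-hazard-ratio weight per planted feature, applied
#'   to `ln(RPM + 1)`.
#' @param baseline_hazard Baseline event rate, events per month.
#' @param censor_rate Intended approximate censoring proportion; documented
#'   target used to choose `accrual_months`, not a direct parameter.
#' @param accrual_months Administrative censoring window: each sample's
#'   censoring time is uniform on (0, `accrual_months`); `Inf` disables
#'   censoring.
#' @param lognormal_sigma Dispersion (SD of log expression) of the
#'   non-dominant features.
#' @param seed Integer seed; identical configs give bit-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 96L,
                       n_mirnas = 2000L,
                       n_dominant = 3L,
                       dominant_fraction = 0.5,
                       planted_features = c("miR-2115-3p", "miR-218-5p",
                                            "miR-224-5p", "miR-4676-3p",
                                            "miR-6503-5p"),
                       planted_weights = rep(0.8, 5L),
                       baseline_hazard = 0.05,
                       censor_rate = 0.4,
                       accrual_months = 36,
                       lognormal_sigma = 1,
                       seed = 1L) {
  if (n_samples < 1 || n_mirnas < 1) {
    stop("configuration error: dimensions must be positive", call. = FALSE)
  }
  if (n_dominant >= n_mirnas) {
    stop("configuration error: n_dominant must be < n_mirnas", call. = FALSE)
  }
  if (dominant_fraction < 0 || dominant_fraction >= 1) {
    stop("configuration error: dominant_fraction must lie in [0, 1)",
         call. = FALSE)
  }
  if (censor_rate < 0 || censor_rate > 1) {
    stop("configuration error: censor_rate must lie in [0, 1]", call. = FALSE)
  }
  if (length(planted_features) != length(planted_weights)) {
    stop("configuration error: planted_features and planted_weights must ",
         "align", call. = FALSE)
  }
  if (anyDuplicated(planted_features)) {
    stop("configuration error: planted_features must be unique",
         call. = FALSE)
  }
  structure(list(
    n_samples = as.integer(n_samples), n_mirnas = as.integer(n_mirnas),
    n_dominant = as.integer(n_dominant),
    dominant_fraction = dominant_fraction,
    planted_features = planted_features,
    planted_weights = as.numeric(planted_weights),
    baseline_hazard = baseline_hazard, censor_rate = censor_rate,
    accrual_months = accrual_months, lognormal_sigma = lognormal_sigma,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Fixed canonical cell-type order; also the deconvolution tie-break order.
#' Canonical blood cell types of the sorted-cell atlas
#' @return Character vector of the 10 cell types in canonical order.
#' @export
blood_cell_types <- function() {
  c("erythrocytes", "platelets", "neutrophils", "eosinophils", "basophils",
    "monocytes", "nk_cells", "cd4_t_cells", "cd8_t_cells", "b_cells")
}

sim_feature_names <- function(config) {
  dominant <- c("miR-486-5p", "miR-451a", "miR-16-5p", "miR-92a-3p",
                "miR-25-3p", "miR-191-5p")[seq_len(config$n_dominant)]
  if (config$n_dominant > 6L) {
    dominant <- c(dominant, sprintf("miR-dom-%02d", seq_len(config$n_dominant - 6L)))
  }
  n_rest <- config$n_mirnas - config$n_dominant
  rest <- sprintf("miR-sim-%04d", seq_len(n_rest))
  planted <- config$planted_features
  planted <- planted[!planted %in% dominant]
  rest[seq_along(planted)] <- planted
  c(dominant, rest)
}

#' Simulate a whole-blood miRNA RPM expression matrix
#'
#' Non-dominant features are log-normal with per-feature baseline abundance;
#' the dominant block is rescaled so that it carries exactly
#' `dominant_fraction` of each sample's RPM mass, emulating the erythroid
#' read-dominance of unblocked whole-blood libraries. Every row sums to 1e6
#' (RPM closure) up to floating-point error.
#'
#' @param config A [sim_config()].
#' @return Numeric matrix, samples x miRNAs, in RPM. Planted feature names
#'   are guaranteed present as columns.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  m <- config$n_mirnas
  feat <- sim_feature_names(config)
  # Per-feature baseline abundance on the log scale. Drawn under a fixed
  # internal seed so that cohorts simulated with different seeds share the
  # same population expression profile (as independent clinical cohorts do)
  # and differ only in sampling noise.
  mu <- with_seed(104729L, stats::rnorm(m, mean = 3, sd = 1.5))
  with_seed(config$seed, {
    z <- matrix(stats::rnorm(n * m, sd = config$lognormal_sigma), n, m)
    x <- exp(sweep(z, 2L, mu, "+"))
    dimnames(x) <- list(sprintf("S%03d", seq_len(n)), feat)
    dom <- seq_len(config$n_dominant)
    f <- config$dominant_fraction
    if (config$n_dominant > 0L && f > 0) {
      # dominant features get a large abundance offset before block rescaling
      x[, dom] <- x[, dom, drop = FALSE] * exp(8)
      dom_mass <- rowSums(x[, dom, drop = FALSE])
      rest_mass <- rowSums(x[, -dom, drop = FALSE])
      x[, dom] <- x[, dom, drop = FALSE] * (f * 1e6 / dom_mass)
      x[, -dom] <- x[, -dom, drop = FALSE] * ((1 - f) * 1e6 / rest_mass)
    } else {
      x <- x * (1e6 / rowSums(x))
    }
    x
  })
}

#' Simulate survival outcomes from planted expression effects
#'
#' Event times are exponential with per-sample hazard
#' `baseline_hazard * exp(lp - mean(lp))` where the linear predictor `lp` is
#' the planted-weight combination of `ln(RPM + 1)`; mean-centering keeps the
#' baseline hazard interpretable as the typical event rate. Censoring times
#' are independent uniform(0, `accrual_months`); the observed time is the
#' minimum and the event indicator marks observed deaths.
#'
#' @param expression RPM matrix from [simulate_expression()].
#' @param config The same [sim_config()].
#' @return List with `survival` (data.frame: `time`, `event`) and
#'   `ground_truth` (list: `planted_features`, `planted_weights`,
#'   `true_linear_predictor` — the uncentered planted score — and
#'   `censoring_times`).
#' @export
simulate_survival <- function(expression, config) {
  stopifnot(inherits(config, "sim_config"))
  missing <- setdiff(config$planted_features, colnames(expression))
  if (length(missing)) {
    stop("feature error: planted feature(s) not in expression: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(expression)
  lp <- drop(log1p(expression[, config$planted_features, drop = FALSE]) %*%
               config$planted_weights)
  with_seed(config$seed + 1L, {
    hazard <- config$baseline_hazard * exp(lp - mean(lp))
    event_time <- stats::rexp(n, rate = hazard)
    cens_time <- if (is.finite(config$accrual_months)) {
      stats::runif(n, 0, config$accrual_months)
    } else {
      rep(Inf, n)
    }
    time <- pmin(event_time, cens_time)
    event <- as.integer(event_time <= cens_time)
    list(
      survival = data.frame(time = time, event = event,
                            row.names = rownames(expression)),
      ground_truth = list(planted_features = config$planted_features,
                          planted_weights = config$planted_weights,
                          true_linear_predictor = unname(lp),
                          censoring_times = cens_time)
    )
  })
}

# Gaussian-copula draw: correlates a latent normal with the (standardised)
# planted linear predictor while preserving requested marginal frequencies.
copula_categorical <- function(z_lp, association, freqs) {
  n <- length(z_lp)
  latent <- association * z_lp + sqrt(1 - association^2) * stats::rnorm(n)
  p <- freqs / sum(freqs)
  cuts <- stats::qnorm(cumsum(p)[-length(p)])
  labels <- names(freqs)
  idx <- findInterval(latent, cuts) + 1L
  factor(labels[idx], levels = labels)
}

#' Simulate Table-1-like clinical covariates
#'
#' Generates PD-L1 TPS category, ECOG, sex, age, therapy line, substance,
#' histology, smoking status, ANC and ALC with marginal frequencies defaulting
#' to the training-cohort distribution and an optional Gaussian-copula
#' association to the planted linear predictor (categories are ordered from
#' low to high risk, so positive association ties high-risk categories to
#' shorter survival).
#'
#' @param survival data.frame from [simulate_survival()] (used for its sample
#'   count and row names).
#' @param config The [sim_config()].
#' @param association Copula correlation in [0, 1) between covariates and the
#'   planted linear predictor; 0 (default) makes covariates independent of
#'   outcome.
#' @param ground_truth Optional ground-truth list (required when
#'   `association > 0`).
#' @param frequencies Optional named list overriding marginal category counts
#'   or proportions; entries `pd_l1`, `ecog`, `sex`, `therapy_line`,
#'   `substance`, `histology`, `smoking`.
#' @return data.frame with the covariate columns described above.
#' @export
simulate_clinical <- function(survival, config, association = 0,
                              ground_truth = NULL, frequencies = list()) {
  stopifnot(inherits(config, "sim_config"), association >= 0, association < 1)
  n <- nrow(survival)
  if (association > 0 && is.null(ground_truth)) {
    stop("ground_truth required when association > 0", call. = FALSE)
  }
  z_lp <- if (association > 0) {
    lp <- ground_truth$true_linear_predictor
    as.numeric(scale(lp))
  } else {
    rep(0, n)
  }
  def <- list(
    pd_l1 = c(">=50" = 68, "1-49" = 20, "<1" = 8),  # high TPS = lower risk
    ecog = c("0" = 35, "1" = 56, "2" = 5),
    sex = c(female = 36, male = 60),
    therapy_line = c("1" = 47, "2" = 46, "3" = 3),
    substance = c(pembrolizumab = 74, nivolumab = 22),
    histology = c(adeno = 56, squamous = 27, other = 13),
    smoking = c(never = 8, former = 56, current = 32)
  )
  for (nm in names(frequencies)) def[[nm]] <- frequencies[[nm]]
  with_seed(config$seed + 2L, {
    clin <- data.frame(
      pd_l1_category = copula_categorical(z_lp, association, def$pd_l1),
      ecog = copula_categorical(z_lp, association, def$ecog),
      sex = copula_categorical(z_lp, association, def$sex),
      age = round(pmin(95, pmax(30, 67.6 + 9.4 *
        (association * z_lp + sqrt(1 - association^2) * stats::rnorm(n)))), 1),
      therapy_line = as.integer(as.character(
        copula_categorical(z_lp, association, def$therapy_line))),
      substance = copula_categorical(z_lp, association, def$substance),
      histology = copula_categorical(z_lp, association, def$histology),
      smoking = copula_categorical(z_lp, association, def$smoking),
      anc = round(exp(log(5) + 0.35 *
        (association * z_lp + sqrt(1 - association^2) * stats::rnorm(n))), 2),
      alc = round(exp(log(1.5) + 0.4 *
        (-association * z_lp + sqrt(1 - association^2) * stats::rnorm(n))), 2),
      row.names = rownames(survival)
    )
    clin
  })
}

#' Simulate a sorted-cell miRNA atlas with per-donor metadata
#'
#' Emulates small RNA-seq of the 10 canonical blood cell populations sorted
#' from 12 healthy donors: an RPM array (miRNA x cell type x donor) plus the
#' per-donor, per-cell-type quantities that enter the deconvolution scaling
#' factor (elution volume, small RNA concentration, sorted cell count, blood
#' count per ml). A configurable leading block of miRNAs is expressed in
#' exactly one cell type (round-robin), giving planted cell-of-origin truth.
#'
#' @param config The [sim_config()].
#' @param n_donors Number of donors (study design: 12).
#' @param n_exclusive Number of leading miRNAs restricted to a single cell
#'   type.
#' @param donor_cv Multiplicative log-normal donor-to-donor noise SD (0 gives
#'   identical donors).
#' @return List with `atlas` (3-d array, miRNA x cell type x donor, RPM),
#'   `metadata` (data.frame, one row per donor x cell type), and
#'   `exclusive_truth` (named vector: planted cell type per exclusive miRNA).
#' @export
simulate_cell_atlas <- function(config, n_donors = 12L, n_exclusive = 100L,
                                donor_cv = 0.3) {
  stopifnot(inherits(config, "sim_config"), n_exclusive <= config$n_mirnas)
  cells <- blood_cell_types()
  feat <- sim_feature_names(config)
  m <- config$n_mirnas
  with_seed(config$seed + 3L, {
    # mean profile per (miRNA, cell type)
    base <- matrix(exp(stats::rnorm(m * length(cells), 3, 1.5)), m,
                   dimnames = list(feat, cells))
    excl <- character(0)
    if (n_exclusive > 0L) {
      excl_cells <- rep_len(cells, n_exclusive)
      for (i in seq_len(n_exclusive)) {
        base[i, ] <- 0
        base[i, excl_cells[i]] <- exp(stats::rnorm(1, 5, 1))
      }
      excl <- stats::setNames(excl_cells, feat[seq_len(n_exclusive)])
    }
    atlas <- array(0, dim = c(m, length(cells), n_donors),
                   dimnames = list(feat, cells,
                                   sprintf("D%02d", seq_len(n_donors))))
    for (p in seq_len(n_donors)) {
      noise <- matrix(exp(stats::rnorm(m * length(cells), 0, donor_cv)), m)
      xp <- base * noise
      atlas[, , p] <- sweep(xp, 2L, colSums(xp), "/") * 1e6  # per-library RPM
    }
    # rough physiologic blood concentrations (cells per ml)
    blood <- c(erythrocytes = 5e9, platelets = 2.5e8, neutrophils = 4e6,
               eosinophils = 2e5, basophils = 4e4, monocytes = 5e5,
               nk_cells = 2e5, cd4_t_cells = 7e5, cd8_t_cells = 4e5,
               b_cells = 2e5)
    meta <- expand.grid(donor = dimnames(atlas)[[3]], cell_type = cells,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    nr <- nrow(meta)
    meta$V_elution_ul <- 18
    meta$c_sRNA_ng_per_ul <- round(exp(stats::rnorm(nr, log(2), 0.4)), 3)
    meta$n_sorted <- round(exp(stats::rnorm(nr, log(5e6), 0.5)))
    meta$n_blood_per_ml <- round(blood[meta$cell_type] *
                                   exp(stats::rnorm(nr, 0, 0.2)))
    list(atlas = atlas, metadata = meta, exclusive_truth = excl)
  })
}

#' Simulate triplicate qPCR Ct values from NGS expression
#'
#' `Ct = intercept - slope * log2(RPM + 1) + N(0, noise_sd)`, measured in
#' `n_replicates` technical replicates per sample and assay; lower Ct means
#' higher expression.
#'
#' @param expression RPM matrix.
#' @param targets Target assay feature names (e.g. the signature miRNAs).
#' @param housekeepers Housekeeping assay feature names; must not overlap
#'   targets.
#' @param config The [sim_config()].
#' @param intercept,slope,noise_sd Ct model parameters (cycles).
#' @param n_replicates Technical replicates per sample x assay.
#' @return Long-format data.frame of class `ct_matrix`: `sample`, `assay`,
#'   `role` ("target"/"housekeeper"), `replicate`, `ct`.
#' @export
simulate_qpcr <- function(expression, targets, housekeepers, config,
                          intercept = 40, slope = 1, noise_sd = 0.25,
                          n_replicates = 3L) {
  stopifnot(inherits(config, "sim_config"))
  if (length(intersect(targets, housekeepers))) {
    stop("configuration error: targets and housekeepers overlap",
         call. = FALSE)
  }
  assays <- c(targets, housekeepers)
  missing <- setdiff(assays, colnames(expression))
  if (length(missing)) {
    stop("feature error: assay feature(s) not in expression: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  with_seed(config$seed + 4L, {
    grid <- expand.grid(sample = rownames(expression), assay = assays,
                        replicate = seq_len(n_replicates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rpm <- expression[cbind(grid$sample, grid$assay)]
    grid$role <- ifelse(grid$assay %in% targets, "target", "housekeeper")
    grid$ct <- intercept - slope * log2(rpm + 1) +
      stats::rnorm(nrow(grid), 0, noise_sd)
    class(grid) <- c("ct_matrix", "data.frame")
    grid[order(grid$sample, grid$assay, grid$replicate), ]
  })
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper running [simulate_expression()], [simulate_survival()]
#' and [simulate_clinical()] under one configuration.
#'
#' @param config A [sim_config()].
#' @param clinical_association Passed to [simulate_clinical()].
#' @return List: `expression`, `survival`, `clinical`, `ground_truth`,
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config(), clinical_association = 0) {
  expr <- simulate_expression(config)
  ss <- simulate_survival(expr, config)
  clin <- simulate_clinical(ss$survival, config,
                            association = clinical_association,
                            ground_truth = ss$ground_truth)
  list(expression = expr, survival = ss$survival, clinical = clin,
       ground_truth = ss$ground_truth, config = config)
}
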