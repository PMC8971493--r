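#' Pearson chi-square test for a contingency table
#'
#' Pearson chi-square with Yates continuity correction applied automatically
#' to 2x2 tables (the convention of the published cohort-comparison table),
#' uncorrected otherwise. `correction` can force either behaviour.
#'
#' @param table Matrix of non-negative counts, at least 2x2.
#' @param correction `"auto"` (Yates iff 2x2), `TRUE`, or `FALSE`.
#' @return List: `chi_square`, `df`, `p_value`.
#' @export
chisq_contingency <- function(table, correction = "auto") {
  tab <- as.matrix(table)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("contingency table must be at least 2x2", call. = FALSE)
  }
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: zero marginal", call. = FALSE)
  }
  correct <- if (identical(correction, "auto")) {
    nrow(tab) == 2L && ncol(tab) == 2L
  } else {
    isTRUE(correction)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi_square = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test with Satterthwaite degrees of freedom.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @return List: `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_ttest <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop("each sample needs n >= 2", call. = FALSE)
  }
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0 &&
      mean(sample_a) == mean(sample_b)) {
    # degenerate: identical constants; report no evidence of difference
    return(list(t = 0, df = Inf, p_value = 1,
                mean_a = mean(sample_a), mean_b = mean(sample_b)))
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value),
       mean_a = mean(sample_a), mean_b = mean(sample_b))
}

#' Cohort characteristics comparison (Table-1-style)
#'
#' For every shared categorical variable, builds the cross-cohort contingency
#' table (rows with NA excluded for that variable only) and applies
#' [chisq_contingency()]; `age` is compared with [welch_ttest()]. P-values
#' are reported to 4 decimal places (full precision retained in `p_full`).
#'
#' @param clinical_a,clinical_b Clinical tables of the two cohorts with the
#'   [simulate_clinical()] column vocabulary.
#' @param variables Variables to compare; defaults to all categorical columns
#'   shared by both cohorts plus `age`.
#' @return data.frame: `variable`, `test`, `statistic`, `df`, `p_value`
#'   (4 dp), `p_full`.
#' @export
cohort_characteristics <- function(clinical_a, clinical_b,
                                   variables = NULL) {
  if (nrow(clinical_a) == 0L || nrow(clinical_b) == 0L) {
    stop("input error: empty cohort", call. = FALSE)
  }
  shared <- intersect(names(clinical_a), names(clinical_b))
  if (is.null(variables)) {
    is_cat <- vapply(shared, function(v) {
      is.factor(clinical_a[[v]]) || is.character(clinical_a[[v]]) ||
        (is.numeric(clinical_a[[v]]) &&
           length(unique(clinical_a[[v]])) <= 6L)
    }, logical(1))
    variables <- c(shared[is_cat & shared != "age"],
                   intersect("age", shared))
  }
  rows <- lapply(variables, function(v) {
    if (v == "age") {
      ht <- welch_ttest(clinical_a$age[!is.na(clinical_a$age)],
                        clinical_b$age[!is.na(clinical_b$age)])
      data.frame(variable = v, test = "welch_t", statistic = ht$t,
                 df = ht$df, p_value = round(ht$p_value, 4),
                 p_full = ht$p_value)
    } else {
      a <- clinical_a[[v]][!is.na(clinical_a[[v]])]
      b <- clinical_b[[v]][!is.na(clinical_b[[v]])]
      lev <- sort(unique(c(as.character(a), as.character(b))))
      tab <- rbind(table(factor(a, levels = lev)),
                   table(factor(b, levels = lev)))
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      ht <- chisq_contingency(tab)
      data.frame(variable = v, test = "chisq", statistic = ht$chi_square,
                 df = ht$df, p_value = round(ht$p_value, 4),
                 p_full = ht$p_value)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published cohort counts (training vs independent validation)
#'
#' The printed cross-cohort contingency tables of the study's
#' clinical-characteristics comparison, shipped as reusable input: recruiting
#' site, sex, substance, histology, smoking status and therapy line, plus
#' the age summaries (mean, SD, n). Rows are cohorts (training n=96,
#' validation n=99).
#'
#' @return Named list of count matrices plus an `age` list.
#' @export
nsclc_table1_counts <- function() {
  cohorts <- c("training", "validation")
  list(
    site = matrix(c(96, 0, 84, 15), 2, byrow = TRUE,
                  dimnames = list(cohorts, c("Heidelberg", "Grosshansdorf"))),
    sex = matrix(c(60, 36, 64, 35), 2, byrow = TRUE,
                 dimnames = list(cohorts, c("male", "female"))),
    substance = matrix(c(22, 74, 44, 55), 2, byrow = TRUE,
                       dimnames = list(cohorts, c("nivolumab", "pembrolizumab"))),
    histology = matrix(c(56, 27, 13, 56, 33, 10), 2, byrow = TRUE,
                       dimnames = list(cohorts, c("adeno", "squamous", "other"))),
    smoking = matrix(c(8, 56, 32, 5, 56, 38), 2, byrow = TRUE,
                     dimnames = list(cohorts, c("never", "former", "current"))),
    therapy_line = matrix(c(47, 46, 3, 0, 36, 43, 13, 7), 2, byrow = TRUE,
                          dimnames = list(cohorts, c("1", "2", "3", ">3"))),
    age = list(training = list(mean = 67.6, sd = 9.4, n = 96),
               validation = list(mean = 66.4, sd = 9.4, n = 99))
  )
}

#' Chi-square comparison of the published cohort count tables
#'
#' Runs [chisq_contingency()] on each printed categorical table from
#' [nsclc_table1_counts()].
#'
#' @return data.frame: `variable`, `chi_square`, `df`, `p_value` (4 dp),
#'   `p_full`.
#' @export
table1_statistics <- function() {
  counts <- nsclc_table1_counts()
  vars <- setdiff(names(counts), "age")
  rows <- lapply(vars, function(v) {
    tab <- counts[[v]]
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    ht <- chisq_contingency(tab)
    data.frame(variable = v, chi_square = ht$chi_square, df = ht$df,
               p_value = round(ht$p_value, 4), p_full = ht$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
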