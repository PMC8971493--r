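#' Per-donor, per-cell-type scaling factors
#'
#' `alpha = (V_elution * c_sRNA / n_sorted) * n_blood_per_ml`: the small RNA
#' yield per sorted cell times the cell type's abundance in blood, i.e. ng of
#' small RNA contributed per ml of blood. These factors place each sorted
#' population's RPM profile on a common whole-blood scale.
#'
#' @param metadata data.frame with columns `donor`, `cell_type`,
#'   `V_elution_ul`, `c_sRNA_ng_per_ul`, `n_sorted`, `n_blood_per_ml` (one
#'   row per donor x cell type).
#' @return Numeric matrix, cell types x donors.
#' @export
scaling_factor <- function(metadata) {
  req <- c("donor", "cell_type", "V_elution_ul", "c_sRNA_ng_per_ul",
           "n_sorted", "n_blood_per_ml")
  missing <- setdiff(req, names(metadata))
  if (length(missing)) {
    stop("metadata error: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num <- metadata[c("V_elution_ul", "c_sRNA_ng_per_ul", "n_sorted",
                    "n_blood_per_ml")]
  if (any(!is.finite(as.matrix(num))) || any(as.matrix(num) <= 0)) {
    stop("metadata error: all quantities must be positive and finite",
         call. = FALSE)
  }
  a <- metadata$V_elution_ul * metadata$c_sRNA_ng_per_ul /
    metadata$n_sorted * metadata$n_blood_per_ml
  cells <- unique(metadata$cell_type)
  donors <- unique(metadata$donor)
  alpha <- matrix(NA_real_, length(cells), length(donors),
                  dimnames = list(cells, donors))
  alpha[cbind(metadata$cell_type, metadata$donor)] <- a
  if (anyNA(alpha)) {
    stop("metadata error: incomplete donor x cell type grid", call. = FALSE)
  }
  alpha
}

#' Scaled mean expression per miRNA and cell type
#'
#' `xbar[m, c] = (1/P) * sum_p x[m, c, p] * alpha[c, p]`: donor-averaged,
#' abundance-scaled expression of each miRNA in each cell type.
#'
#' @param atlas 3-d RPM array, miRNA x cell type x donor (see
#'   [simulate_cell_atlas()]).
#' @param alpha Scaling-factor matrix from [scaling_factor()], cell types x
#'   donors.
#' @return Matrix, miRNA x cell type.
#' @export
scaled_mean_expression <- function(atlas, alpha) {
  d <- dim(atlas)
  if (length(d) != 3L) stop("shape error: atlas must be 3-dimensional",
                            call. = FALSE)
  if (!all(d[2:3] == dim(alpha))) {
    stop("shape error: alpha must be cell types x donors matching the atlas",
         call. = FALSE)
  }
  if (!is.null(dimnames(atlas)[[2]]) && !is.null(rownames(alpha))) {
    alpha <- alpha[dimnames(atlas)[[2]], dimnames(atlas)[[3]], drop = FALSE]
  }
  P <- d[3]
  xbar <- matrix(0, d[1], d[2], dimnames = dimnames(atlas)[1:2])
  for (p in seq_len(P)) {
    xbar <- xbar + sweep(atlas[, , p, drop = TRUE], 2L, alpha[, p], "*")
  }
  xbar / P
}

#' Cell-type proportions per miRNA
#'
#' Row-normalises the scaled means: `prop[m, c] = xbar[m, c] / sum_c
#' xbar[m, c]`. miRNAs with zero total scaled expression cannot be
#' attributed; they are flagged (all-NA row) rather than dropped silently.
#'
#' @param xbar Matrix from [scaled_mean_expression()].
#' @return Matrix of proportions (rows sum to 1; unattributed rows are NA)
#'   with attribute `unattributed` listing the flagged miRNAs.
#' @export
cell_type_proportions <- function(xbar) {
  if (any(xbar < 0, na.rm = TRUE)) {
    stop("scaled means must be non-negative", call. = FALSE)
  }
  tot <- rowSums(xbar)
  prop <- xbar / tot
  prop[tot == 0, ] <- NA_real_
  attr(prop, "unattributed") <- rownames(xbar)[tot == 0]
  prop
}

#' Dominant cell type per miRNA
#'
#' Argmax cell type of each miRNA's proportion vector; ties are broken by the
#' fixed canonical cell-type order ([blood_cell_types()], or the atlas column
#' order if the columns are not the canonical set). Unattributed (all-NA)
#' miRNAs are skipped.
#'
#' @param prop Proportion matrix from [cell_type_proportions()].
#' @return List: `dominant` (named character vector, one entry per attributed
#'   miRNA), `counts` (per-cell-type histogram over attributed miRNAs, in
#'   tie-break order).
#' @export
dominant_cell_type <- function(prop) {
  cells <- colnames(prop)
  canon <- intersect(blood_cell_types(), cells)
  ord <- if (length(canon) == length(cells)) canon else cells
  prop <- prop[, ord, drop = FALSE]
  ok <- !apply(prop, 1L, function(r) all(is.na(r)))
  dom <- apply(prop[ok, , drop = FALSE], 1L,
               function(r) ord[which.max(r)])  # which.max: first max wins
  counts <- table(factor(dom, levels = ord))
  list(dominant = dom, counts = counts)
}

#' Run the full deconvolution
#'
#' Scaling factors, scaled means, proportions and dominant assignments in one
#' call.
#'
#' @inheritParams scaled_mean_expression
#' @param metadata See [scaling_factor()].
#' @return List of class `deconvolution_result`: `alpha`, `xbar`, `prop`,
#'   `dominant`, `counts`, `unattributed`.
#' @export
deconvolve_atlas <- function(atlas, metadata) {
  alpha <- scaling_factor(metadata)
  xbar <- scaled_mean_expression(atlas, alpha)
  prop <- cell_type_proportions(xbar)
  dom <- dominant_cell_type(prop)
  structure(list(alpha = alpha, xbar = xbar, prop = prop,
                 dominant = dom$dominant, counts = dom$counts,
                 unattributed = attr(prop, "unattributed")),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat("Cell-of-origin deconvolution:", nrow(x$prop), "miRNAs x",
      ncol(x$prop), "cell types\n")
  cat("dominant-assignment counts:\n")
  print(x$counts)
  if (length(x$unattributed)) {
    cat(length(x$unattributed), "miRNA(s) unattributed (zero scaled total)\n")
  }
  invisible(x)
}

#' Correlation of miRNA expression with blood cell counts
#'
#' Pearson correlation (with two-sided p) between each miRNA's RPM values and
#' each cell type's blood count across samples. Per cell type, samples whose
#' count exceeds `mean + exclusion_sd * SD` are excluded first (the study
#' excluded one sample at 5.2 SD above the mean monocyte count); exclusions
#' are reported.
#'
#' @param expression RPM matrix, samples x miRNAs.
#' @param counts Matrix or data.frame of blood counts, samples x cell types.
#' @param exclusion_sd Outlier threshold in SD units (default 5).
#' @return List: `r` and `p` (miRNA x cell type matrices), `excluded` (named
#'   list of excluded sample indices per cell type).
#' @export
expression_count_correlation <- function(expression, counts,
                                         exclusion_sd = 5) {
  x <- as.matrix(expression)
  cnt <- as.matrix(counts)
  if (nrow(x) != nrow(cnt)) {
    stop("expression and counts describe different samples", call. = FALSE)
  }
  r <- p <- matrix(NA_real_, ncol(x), ncol(cnt),
                   dimnames = list(colnames(x), colnames(cnt)))
  excluded <- list()
  for (ct in seq_len(ncol(cnt))) {
    v <- cnt[, ct]
    keep <- v <= mean(v) + exclusion_sd * stats::sd(v)
    excluded[[colnames(cnt)[ct]]] <- which(!keep)
    if (sum(keep) < 3L) {
      stop("insufficient data: fewer than 3 samples remain for ",
           colnames(cnt)[ct], call. = FALSE)
    }
    for (m in seq_len(ncol(x))) {
      ht <- suppressWarnings(stats::cor.test(x[keep, m], v[keep]))
      r[m, ct] <- unname(ht$estimate)
      p[m, ct] <- ht$p.value
    }
  }
  list(r = r, p = p, excluded = excluded)
}
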