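#' Read / write an RPM expression matrix as TSV
#'
#' Rows are samples, columns are miRNAs; the first column holds sample IDs.
#'
#' @param path File path.
#' @param expression Samples x miRNAs matrix.
#' @return `read_expression_tsv` returns a numeric matrix with dimnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  as.matrix(df)
}

#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(expression, path) {
  df <- data.frame(sample = rownames(expression),
                   as.data.frame(expression, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a full synthetic cohort to a directory
#'
#' Emits `expression.tsv`, `survival.csv`, `clinical.csv` and
#' `ground_truth.json`.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Target directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.csv(data.frame(sample = rownames(cohort$survival),
                              cohort$survival),
                   file.path(dir, "survival.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sample = rownames(cohort$clinical),
                              cohort$clinical),
                   file.path(dir, "clinical.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
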