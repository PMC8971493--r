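#' The frozen published miRisk signature
#'
#' The five-miRNA whole-blood risk score for overall survival under PD-1
#' inhibitor monotherapy, with its published coefficients
#' (miR-2115-3p 1.870, miR-218-5p 0.907, miR-224-5p 0.495, miR-4676-3p 1.309,
#' miR-6503-5p 1.159) on `ln(RPM + 1)` and the published median cutpoint
#' 5.61. Shipped as a JSON asset and loaded verbatim.
#'
#' @return A `mirna_signature` object.
#' @examples
#' mirisk_signature()
#' @export
mirisk_signature <- function() {
  path <- system.file("extdata", "mirisk_signature.json", package = "mirisk",
                      mustWork = TRUE)
  read_signature_json(path)
}

#' Evaluate the miRisk score
#'
#' `miRisk = 1.870 ln(miR-2115-3p + 1) + 0.907 ln(miR-218-5p + 1) +
#'  0.495 ln(miR-224-5p + 1) + 1.309 ln(miR-4676-3p + 1) +
#'  1.159 ln(miR-6503-5p + 1)` with RPM inputs. All five miRNAs must be
#' present; a missing feature raises an error naming the absentee.
#'
#' @param expression RPM matrix (samples x miRNAs) or a single named
#'   expression row.
#' @return Numeric risk score(s); stratify at the frozen cutpoint 5.61 with
#'   [stratify()].
#' @examples
#' rpm <- setNames(rep(exp(1) - 1, 5), mirisk_signature()$features$mirna)
#' mirisk_score(rpm)  # each log term is 1 -> sum of the coefficients
#' @export
mirisk_score <- function(expression) {
  signature_score(mirisk_signature(), expression)
}

#' Write / read a signature as JSON
#'
#' The on-disk form is
#' `{"features":[{"mirna":...,"weight":...},...],"cutpoint":...,
#' "transform":"ln1p","provenance":...}`.
#'
#' @param signature A `mirna_signature`.
#' @param path File path.
#' @return `read_signature_json` returns a `mirna_signature`;
#'   `write_signature_json` returns `path` invisibly.
#' @export
write_signature_json <- function(signature, path) {
  stopifnot(inherits(signature, "mirna_signature"))
  obj <- list(features = signature$features, cutpoint = signature$cutpoint,
              transform = signature$transform,
              provenance = signature$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_signature_json
#' @export
read_signature_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(obj$transform, "ln1p"))
  new_signature(features = data.frame(mirna = obj$features$mirna,
                                      weight = as.numeric(obj$features$weight)),
                cutpoint = as.numeric(obj$cutpoint),
                provenance = as.character(obj$provenance))
}
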