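#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
# All stochastic entry points route their seed through here so that a given
# seed yields bit-identical output regardless of surrounding RNG usage.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Coerce (time, event) input into a validated two-column data.frame.
# Accepts a data.frame with `time` and `event` columns or a list of the same.
as_survival_data <- function(survival) {
  if (is.matrix(survival)) survival <- as.data.frame(survival)
  if (!is.list(survival) || is.null(survival$time) || is.null(survival$event)) {
    stop("`survival` must contain `time` and `event` components", call. = FALSE)
  }
  time <- as.numeric(survival$time)
  event <- as.integer(survival$event)
  if (length(time) != length(event)) {
    stop("`time` and `event` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("survival times must be finite and non-negative", call. = FALSE)
  }
  if (!all(event %in% c(0L, 1L))) {
    stop("event indicator must be 0 (censored) or 1 (death)", call. = FALSE)
  }
  data.frame(time = time, event = event)
}

require_events <- function(surv, n = 1L) {
  if (sum(surv$event) < n) {
    stop("at least ", n, " observed event(s) required", call. = FALSE)
  }
  invisible(surv)
}

# Matrix coercion keeping dimnames; used at every covariate entry point.
as_covariate_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("covariates must not contain missing values", call. = FALSE)
  x
}
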