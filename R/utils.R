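#' Derive a stage-specific seed from a global seed
#'
#' All stochastic stages of the pipeline draw their seeds through this rule so
#' that a single global seed reproduces any partial re-run of the pipeline.
#' The derived seed is `(seed * 48271 + offset) mod (2^31 - 1)`, a
#' Lehmer-style mixing that keeps results inside the 32-bit integer range.
#'
#' @param seed integer global seed.
#' @param offset non-negative integer identifying the stage (each pipeline
#'   stage uses a fixed documented offset).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(as.double(seed)) %% m) * 48271 + as.double(offset)
  as.integer(s %% m + 1)
}

# internal: consistent error signalling
abort_domain <- function(msg) stop(msg, call. = FALSE)

# internal: validate probability vector
check_probs <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
    abort_domain(sprintf("%s must be nonnegative and sum to 1", what))
  invisible(p)
}

# internal: columns of the cohort table that carry outcomes
OUTCOME_COLS <- c("time", "event")
COVARIATE_COLS <- c("siri", "kps", "bmi", "smoking")
SMOKING_LEVELS <- c("never", "former", "current")

# internal: check that a data.frame looks like a cohort table
check_cohort <- function(cohort, need_outcomes = FALSE) {
  if (!is.data.frame(cohort))
    abort_domain("cohort must be a data.frame")
  if (need_outcomes) {
    if (!all(OUTCOME_COLS %in% names(cohort)))
      abort_domain("cohort lacks outcome columns time/event")
    if (anyNA(cohort$time) || anyNA(cohort$event))
      abort_domain("time and event must be fully observed")
    if (any(cohort$time < 0))
      abort_domain("negative follow-up times are not allowed")
    if (!all(cohort$event %in% c(0, 1)))
      abort_domain("event must be 0 (censored) or 1 (death)")
  }
  invisible(cohort)
}
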