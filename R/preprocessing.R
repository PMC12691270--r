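#' Compute the systemic inflammation response index
#'
#' SIRI = neutrophils x monocytes / lymphocytes, from a pre-treatment
#' complete blood count. All counts are in 10^9 cells/L; SIRI is
#' dimensionless and scale-consistent (multiplying all three counts by c
#' multiplies SIRI by c).
#'
#' @param neutrophils,monocytes,lymphocytes absolute counts (> 0); vectors
#'   are recycled to a common length.
#' @return numeric SIRI values.
#' @export
compute_siri <- function(neutrophils, monocytes, lymphocytes) {
  if (any(neutrophils < 0, na.rm = TRUE) || any(monocytes < 0, na.rm = TRUE))
    abort_domain("blood counts must be nonnegative")
  if (any(lymphocytes <= 0, na.rm = TRUE))
    abort_domain("lymphocyte count must be strictly positive")
  neutrophils * monocytes / lymphocytes
}

#' Categorize body-mass index into WHO classes
#'
#' Underweight < 18.5, normal `[18.5, 25)`, overweight `[25, 30)`, obese
#' `[30, Inf)`. Half-open upper intervals ensure every value maps to exactly
#' one class (so 25.0 is overweight and 30.0 is obese).
#'
#' @param bmi numeric kg/m^2 (> 0); `NA` propagates.
#' @return factor with levels underweight/normal/overweight/obese.
#' @export
categorize_bmi <- function(bmi) {
  if (any(bmi <= 0, na.rm = TRUE))
    abort_domain("bmi must be positive")
  cut(bmi, breaks = c(0, 18.5, 25, 30, Inf),
      labels = c("underweight", "normal", "overweight", "obese"),
      right = FALSE)
}

#' Map ECOG performance status to the Karnofsky scale
#'
#' Fixed mapping 0 -> 100, 1 -> 90, 2 -> 60, 3 -> 40, 4 -> 20, respecting
#' the standard ECOG-KPS correspondence. Only the KPS <= 70 dichotomy
#' matters downstream (ECOG >= 2 lands below it).
#'
#' @param ecog integer vector in 0..4; `NA` propagates.
#' @return integer KPS values.
#' @export
map_ecog_to_kps <- function(ecog) {
  ok <- is.na(ecog) | (ecog %in% 0:4)
  if (!all(ok)) abort_domain("ecog must be in 0..4")
  c(100L, 90L, 60L, 40L, 20L)[ecog + 1L]
}

#' Iterative random-forest imputation of missing covariates
#'
#' Missing covariate cells are filled by iterated random-forest regression
#' (numeric columns) or classification (factors), using only the other
#' covariates as predictors — the outcome columns are never read. Columns
#' are initialized with their median (numeric) or mode (factor), then
#' visited in order of increasing missingness for a fixed number of full
#' passes. Observed cells are never altered.
#'
#' Imputation is performed strictly within the supplied table; call it
#' separately on each partition so no information crosses the
#' train/test boundary.
#'
#' @param cohort a cohort `data.frame`; `time`/`event`, if present, must be
#'   fully observed and are ignored by the imputer.
#' @param trees number of trees per forest (default 300).
#' @param iterations number of full passes over incomplete columns
#'   (default 5; no convergence check, by design).
#' @param seed integer seed.
#' @param columns covariate columns eligible for imputation.
#' @param log_scale strictly positive, right-skewed columns imputed on the
#'   log scale (default `"siri"`, which is log-normal in this population);
#'   this avoids the tail shrinkage that regression imputation inflicts on
#'   skewed biomarkers.
#' @return the cohort with missing covariate cells filled.
#' @export
rf_impute <- function(cohort, trees = 300, iterations = 5, seed = 1,
                      columns = COVARIATE_COLS, log_scale = "siri") {
  check_cohort(cohort)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  columns <- intersect(columns, names(cohort))
  x <- cohort[columns]
  log_scale <- intersect(log_scale, columns)
  log_scale <- log_scale[vapply(x[log_scale], function(v)
    is.numeric(v) && all(v > 0, na.rm = TRUE), logical(1))]
  for (cl in log_scale) x[[cl]] <- log(x[[cl]])
  n_miss <- vapply(x, function(v) sum(is.na(v)), integer(1))
  if (any(n_miss == nrow(x)))
    abort_domain(paste("covariate entirely missing:",
                       paste(columns[n_miss == nrow(x)], collapse = ", ")))
  if (all(n_miss == 0)) return(cohort)
  miss_idx <- lapply(x, function(v) which(is.na(v)))
  # initialize with median / mode
  for (cl in columns[n_miss > 0]) {
    v <- x[[cl]]
    fill <- if (is.numeric(v)) stats::median(v, na.rm = TRUE)
            else names(which.max(table(v)))
    v[miss_idx[[cl]]] <- fill
    x[[cl]] <- v
  }
  visit <- columns[n_miss > 0][order(n_miss[n_miss > 0])]
  for (it in seq_len(iterations)) {
    for (cl in visit) {
      idx <- miss_idx[[cl]]
      obs <- setdiff(seq_len(nrow(x)), idx)
      fit <- ranger::ranger(
        x = x[obs, setdiff(columns, cl), drop = FALSE],
        y = x[[cl]][obs],
        num.trees = trees, num.threads = 1,
        seed = derive_seed(seed, 1000L + 10L * it + match(cl, columns)),
        respect.unordered.factors = "order")
      # classification tie-breaks in prediction are randomized unless seeded
      pred <- stats::predict(fit, x[idx, setdiff(columns, cl), drop = FALSE],
                             num.threads = 1,
                             seed = derive_seed(seed, 2000L + 10L * it +
                                                  match(cl, columns)))$predictions
      x[[cl]][idx] <- pred
    }
  }
  for (cl in log_scale) x[[cl]] <- exp(x[[cl]])
  cohort[columns] <- x
  cohort
}

#' Randomly split a cohort 70/30 into training/validation and test sets
#'
#' A uniformly random partition drawn before any model training; the
#' training fraction is `round(frac * n)` patients.
#'
#' @param cohort a cohort `data.frame` with `n >= 10` rows.
#' @param seed integer seed; the split is deterministic given `(n, seed)`.
#' @param frac training fraction (default 0.70).
#' @return factor of length `n` with levels `train_validation`, `test`.
#' @export
split_cohort <- function(cohort, seed, frac = 0.70) {
  n <- nrow(cohort)
  if (n < 10) abort_domain("need at least 10 subjects to split")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 404L))
  n_train <- round(frac * n)
  lab <- rep("test", n)
  lab[sample.int(n, n_train)] <- "train_validation"
  factor(lab, levels = c("train_validation", "test"))
}
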