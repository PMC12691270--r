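#' Covariate specification for the synthetic cohort generator
#'
#' Defaults emulate the covariate marginals of a published oropharyngeal
#' cancer cohort: SIRI is log-normal with median near 1.34; Karnofsky
#' performance status (KPS) falls in the reporting bands 100 / 80-90 / 70-40
#' with probabilities 27/64/9 percent; smoking history is never/former/current
#' with probabilities 31/54/15 percent. The SIRI location (median 1.42) and
#' log-scale spread (0.8) are chosen so that the cohort quartiles stay within
#' 15 percent of the reported 0.88 / 1.34 / 2.19 while the high-SIRI stratum
#' above 3.5 comfortably exceeds 10 percent of patients, the minimum group
#' size the downstream tree can represent.
#'
#' @param siri_log_mean log-scale location of the SIRI distribution.
#' @param siri_log_sd log-scale spread of the SIRI distribution (> 0).
#' @param kps_band_probs probabilities of the KPS bands 100, 80-90, 70-40;
#'   must sum to 1.
#' @param smoking_probs probabilities of never/former/current smoking;
#'   must sum to 1.
#' @param bmi_mean,bmi_sd body-mass index mean and sd in kg/m^2.
#' @param missing_rate fraction of covariate cells set missing completely at
#'   random, in `[0, 1)`.
#' @return an object of class `covariate_spec`.
#' @export
covariate_spec <- function(siri_log_mean = log(1.42),
                           siri_log_sd = 0.8,
                           kps_band_probs = c(0.27, 0.64, 0.09),
                           smoking_probs = c(0.31, 0.54, 0.15),
                           bmi_mean = 28,
                           bmi_sd = 5.5,
                           missing_rate = 0.02) {
  check_probs(kps_band_probs, "kps_band_probs")
  check_probs(smoking_probs, "smoking_probs")
  if (siri_log_sd <= 0 || bmi_sd <= 0)
    abort_domain("spread parameters must be positive")
  if (missing_rate < 0 || missing_rate >= 1)
    abort_domain("missing_rate must be in [0, 1)")
  structure(list(siri_log_mean = siri_log_mean, siri_log_sd = siri_log_sd,
                 kps_band_probs = kps_band_probs, smoking_probs = smoking_probs,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 missing_rate = missing_rate),
            class = "covariate_spec")
}

#' Hazard specification for the synthetic survival process
#'
#' A Weibull proportional-hazards model with step (threshold) effects: the
#' log hazard increases by `log_hr_siri_high` when SIRI >= `threshold_siri`,
#' by `log_hr_kps_low` when KPS <= `threshold_kps`, and by
#' `log_hr_ever_smoker` for former or current smokers. Follow-up is cut by
#' exponential dropout at `censor_rate` per month and by an administrative
#' horizon. The default effect sizes make the three planted risk groups
#' separable in cohorts of about 600 patients; the default censoring yields
#' a median observed follow-up of roughly 33 months.
#'
#' @param baseline_shape Weibull shape (> 0).
#' @param baseline_scale Weibull scale in months (> 0).
#' @param log_hr_siri_high log hazard ratio of the high-SIRI stratum.
#' @param log_hr_kps_low log hazard ratio of the low-KPS stratum.
#' @param log_hr_ever_smoker log hazard ratio of ever-smokers.
#' @param threshold_siri,threshold_kps planted thresholds (SIRI units, KPS
#'   units).
#' @param censor_rate exponential dropout rate per month (>= 0).
#' @param admin_cutoff administrative censoring horizon in months (> 0, may
#'   be `Inf`).
#' @return an object of class `hazard_spec`.
#' @export
hazard_spec <- function(baseline_shape = 1.1,
                        baseline_scale = 165,
                        log_hr_siri_high = log(6),
                        log_hr_kps_low = log(4.5),
                        log_hr_ever_smoker = log(2.2),
                        threshold_siri = 3.5,
                        threshold_kps = 70,
                        censor_rate = 0.006,
                        admin_cutoff = 84) {
  if (baseline_shape <= 0 || baseline_scale <= 0)
    abort_domain("Weibull shape and scale must be positive")
  if (censor_rate < 0) abort_domain("censor_rate must be >= 0")
  if (admin_cutoff <= 0) abort_domain("admin_cutoff must be positive")
  structure(list(baseline_shape = baseline_shape, baseline_scale = baseline_scale,
                 log_hr_siri_high = log_hr_siri_high, log_hr_kps_low = log_hr_kps_low,
                 log_hr_ever_smoker = log_hr_ever_smoker,
                 threshold_siri = threshold_siri, threshold_kps = threshold_kps,
                 censor_rate = censor_rate, admin_cutoff = admin_cutoff),
            class = "hazard_spec")
}

#' Sample covariates for a synthetic cohort
#'
#' SIRI is drawn log-normally; KPS is drawn by reporting band (100, 80-90,
#' 70-40) and then uniformly over the scale's 10-point values within the
#' band, so the variable keeps its native granularity; smoking and BMI are
#' drawn from the spec. A missing completely at random mask is applied to
#' covariate cells only.
#'
#' @param spec a [covariate_spec()].
#' @param n number of patients (>= 1).
#' @param seed integer seed; the draw is deterministic given
#'   `(spec, n, seed)`.
#' @param apply_missing apply the MCAR mask (set `FALSE` to obtain the
#'   complete covariates, e.g. for planted-truth bookkeeping).
#' @return a cohort `data.frame` with columns `id`, `siri`, `kps`, `bmi`,
#'   `smoking`; outcome columns are absent.
#' @export
sample_covariates <- function(spec, n, seed, apply_missing = TRUE) {
  if (!inherits(spec, "covariate_spec")) spec <- do.call(covariate_spec, spec)
  if (n < 1) abort_domain("n must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 101L))
  siri <- exp(rnorm(n, spec$siri_log_mean, spec$siri_log_sd))
  kps_band <- sample.int(3L, n, replace = TRUE, prob = spec$kps_band_probs)
  # uniform within each reporting band, on the scale's native 10-point grid
  kps <- integer(n)
  kps[kps_band == 1L] <- 100L
  kps[kps_band == 2L] <- sample(c(80L, 90L), sum(kps_band == 2L), replace = TRUE)
  kps[kps_band == 3L] <- sample(c(40L, 50L, 60L, 70L), sum(kps_band == 3L),
                                replace = TRUE)
  smoking <- factor(sample(SMOKING_LEVELS, n, replace = TRUE,
                           prob = spec$smoking_probs),
                    levels = SMOKING_LEVELS)
  bmi <- rnorm(n, spec$bmi_mean, spec$bmi_sd)
  bmi <- pmax(bmi, 12) # physiological floor; essentially never binds
  cohort <- data.frame(id = sprintf("P%05d", seq_len(n)),
                       siri = siri, kps = kps, bmi = bmi, smoking = smoking,
                       stringsAsFactors = FALSE)
  if (apply_missing && spec$missing_rate > 0) {
    for (cl in COVARIATE_COLS) {
      mask <- runif(n) < spec$missing_rate
      cohort[[cl]][mask] <- NA
    }
  }
  cohort
}

#' Sample survival outcomes under the planted-threshold hazard model
#'
#' Event times follow a Weibull proportional-hazards model whose log hazard
#' is the sum of the applicable step increments (SIRI >= threshold,
#' KPS <= threshold, ever-smoker). The observed time is the minimum of the
#' event time, an exponential dropout time, and the administrative cutoff;
#' `event` is 1 iff the event time is the minimum. Missing covariates
#' contribute zero log hazard (generate outcomes before masking, or impute
#' first, when this matters).
#'
#' @param cohort a cohort `data.frame` with covariates.
#' @param hz a [hazard_spec()].
#' @param seed integer seed.
#' @return `cohort` with `time` (months) and `event` (0/1) columns filled.
#' @export
sample_outcomes <- function(cohort, hz, seed) {
  if (!inherits(hz, "hazard_spec")) hz <- do.call(hazard_spec, hz)
  check_cohort(cohort)
  n <- nrow(cohort)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 202L))
  lhr <- rep(0, n)
  siri_high <- !is.na(cohort$siri) & cohort$siri >= hz$threshold_siri
  kps_low <- !is.na(cohort$kps) & cohort$kps <= hz$threshold_kps
  ever <- !is.na(cohort$smoking) & cohort$smoking %in% c("former", "current")
  lhr <- hz$log_hr_siri_high * siri_high + hz$log_hr_kps_low * kps_low +
    hz$log_hr_ever_smoker * ever
  # S(t) = exp(-(t/scale)^shape * HR)  =>  T = scale * (-log U / HR)^(1/shape)
  u <- runif(n)
  t_event <- hz$baseline_scale * (-log(u) / exp(lhr))^(1 / hz$baseline_shape)
  t_cens <- if (hz$censor_rate > 0) rexp(n, hz$censor_rate) else rep(Inf, n)
  t_cens <- pmin(t_cens, hz$admin_cutoff)
  cohort$time <- pmin(t_event, t_cens)
  cohort$event <- as.integer(t_event <= t_cens)
  cohort
}

#' Planted true risk group of a patient
#'
#' Returns the generator's ground-truth group: high SIRI always maps to the
#' worst group regardless of other covariates; otherwise low performance
#' status maps to the worst group; otherwise ever-smokers form the
#' intermediate group and never-smokers the best group.
#'
#' @param patients a `data.frame` with `siri`, `kps`, `smoking` (no missing
#'   values in these columns).
#' @param threshold_siri,threshold_kps thresholds defining the strata.
#' @return integer vector of groups in `{1, 2, 3}` (1 = best prognosis).
#' @export
true_risk_group <- function(patients, threshold_siri = 3.5, threshold_kps = 70) {
  req <- c("siri", "kps", "smoking")
  if (!all(req %in% names(patients)))
    abort_domain("patients must have siri, kps, smoking")
  if (anyNA(patients[req]))
    abort_domain("true_risk_group requires complete siri, kps, smoking")
  ever <- patients$smoking %in% c("former", "current")
  ifelse(patients$siri >= threshold_siri, 3L,
         ifelse(patients$kps <= threshold_kps, 3L,
                ifelse(ever, 2L, 1L)))
}

#' Simulate a complete synthetic cohort with planted truth
#'
#' Covariates are drawn complete, outcomes are generated from the complete
#' covariates, the planted risk group is recorded, and only then is the MCAR
#' mask applied — so the ground truth never depends on the missingness
#' pattern.
#'
#' @inheritParams sample_covariates
#' @param hz a [hazard_spec()].
#' @return a list with `cohort` (masked covariates + outcomes) and `truth`
#'   (complete covariates + `group`).
#' @export
simulate_cohort <- function(n, seed, spec = covariate_spec(), hz = hazard_spec()) {
  complete <- sample_covariates(spec, n, seed, apply_missing = FALSE)
  with_outcomes <- sample_outcomes(complete, hz, seed)
  truth <- complete
  truth$group <- true_risk_group(complete, hz$threshold_siri, hz$threshold_kps)
  cohort <- with_outcomes
  if (spec$missing_rate > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(derive_seed(seed, 303L))
    for (cl in COVARIATE_COLS) {
      mask <- runif(n) < spec$missing_rate
      cohort[[cl]][mask] <- NA
    }
  }
  list(cohort = cohort, truth = truth)
}

#' Write / read a cohort table as delimited text
#'
#' Comma-separated, header row, UTF-8; missing cells are empty strings.
#' Column order is `id,siri,kps,bmi,smoking,time,event` (outcome columns
#' only if present).
#'
#' @param cohort a cohort `data.frame`.
#' @param path file path.
#' @return `read_cohort` returns the cohort `data.frame` with `smoking`
#'   restored as a factor.
#' @export
write_cohort <- function(cohort, path) {
  cols <- intersect(c("id", COVARIATE_COLS, OUTCOME_COLS), names(cohort))
  utils::write.csv(cohort[cols], path, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                       fileEncoding = "UTF-8")
  if ("smoking" %in% names(d))
    d$smoking <- factor(d$smoking, levels = SMOKING_LEVELS)
  d
}

# save/restore the RNG state so generator calls do not disturb the caller's
# random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
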