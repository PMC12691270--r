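# Shared fixtures, all generated in code.

# small complete cohort with outcomes, no missingness
tiny_cohort <- function(n = 120, seed = 42, missing_rate = 0) {
  simulate_cohort(n, seed,
                  spec = covariate_spec(missing_rate = missing_rate))$cohort
}

# a fitted forest on a default synthetic training set (memoised per session)
fitted_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_cohort(600, 11)
      part <- split_cohort(sim$cohort, 11)
      train <- rf_impute(sim$cohort[part == "train_validation", ],
                         seed = derive_seed(11, 1))
      test <- rf_impute(sim$cohort[part == "test", ],
                        seed = derive_seed(11, 2))
      model <- fit_rsf(train, seed = 11)
      cache <<- list(sim = sim, part = part, train = train, test = test,
                     model = model)
    }
    cache
  }
})

# brute-force Harrell C-index: plain double loop over all ordered pairs,
# following the stated evaluability rule (earlier time must be an event,
# tied times never evaluable)
brute_cindex <- function(risk, time, event) {
  conc <- 0; n_pairs <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || time[i] >= time[j]) next
    if (event[i] != 1) next
    n_pairs <- n_pairs + 1
    if (risk[i] > risk[j]) conc <- conc + 1
    else if (risk[i] == risk[j]) conc <- conc + 0.5
  }
  if (n_pairs == 0) stop("no evaluable pairs")
  conc / n_pairs
}

# KM survival at a horizon, computed directly from survival::survfit
km_surv_at_test <- function(time, event, h) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  j <- findInterval(h, sf$time)
  if (j == 0) 1 else sf$surv[j]
}

# hand-rolled two-group log-rank statistic (observed minus expected form),
# independent of survival::survdiff
hand_logrank <- function(time, event, group2) {
  stopifnot(is.logical(group2))
  tt <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in tt) {
    at_risk <- time >= t
    n <- sum(at_risk); n2 <- sum(at_risk & group2)
    d <- sum(time == t & event == 1)
    d2 <- sum(time == t & event == 1 & group2)
    O <- O + d2
    E <- E + d * n2 / n
    if (n > 1) V <- V + d * (n2 / n) * (1 - n2 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
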