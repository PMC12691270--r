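#' Kaplan-Meier survival curve
#'
#' Product-limit estimate with Greenwood standard errors.
#'
#' @param time observed times (>= 0).
#' @param event event indicators (1 = event, 0 = censored).
#' @return an object of class `survival_curve`: `data.frame` with columns
#'   `time` (ordered event/censoring times), `survival`, `at_risk`,
#'   `greenwood_se`.
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0)) abort_domain("negative times are not allowed")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(data.frame(time = sf$time, survival = sf$surv,
                       at_risk = sf$n.risk, greenwood_se = sf$std.err * sf$surv),
            class = c("survival_curve", "data.frame"))
}

#' k-group log-rank test
#'
#' Chi-square statistic with k-1 degrees of freedom and two-sided p-value.
#'
#' @param groups group labels (at least 2 non-empty groups).
#' @param time observed times.
#' @param event event indicators.
#' @return list with `statistic`, `df`, `p`.
#' @export
logrank_test <- function(groups, time, event) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2)
    abort_domain("log-rank test needs at least 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  df <- nlevels(groups) - 1
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Pairwise Cox hazard ratios between risk groups
#'
#' For every unordered pair of groups a two-group Cox proportional hazards
#' model (Breslow tie handling) is fitted; Wald 95 percent confidence
#' intervals and p-values are reported, with Holm-Bonferroni adjustment
#' across the comparisons. Pairs where one group has no events are flagged
#' rather than silently dropped.
#'
#' @param groups group labels.
#' @param time observed times.
#' @param event event indicators.
#' @return `data.frame` with columns `comparison`, `hr`, `ci_low`,
#'   `ci_high`, `p_raw`, `p_adjusted`, `flag`.
#' @export
cox_pairwise_hr <- function(groups, time, event) {
  groups <- droplevels(factor(groups))
  levs <- levels(groups)
  if (length(levs) < 2) abort_domain("need at least 2 groups")
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    sel <- groups %in% pr
    g <- factor(groups[sel], levels = pr)
    lab <- paste(pr[2], "vs", pr[1])
    if (any(tapply(event[sel], g, sum) == 0))
      return(data.frame(comparison = lab, hr = NA, ci_low = NA, ci_high = NA,
                        p_raw = NA, flag = "no events in one group"))
    fit <- survival::coxph(survival::Surv(time[sel], event[sel]) ~ g,
                           ties = "breslow")
    b <- stats::coef(fit)[1]
    se <- sqrt(stats::vcov(fit)[1, 1])
    data.frame(comparison = lab, hr = exp(b),
               ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
               p_raw = 2 * stats::pnorm(-abs(b / se)), flag = "")
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  ok <- !is.na(out$p_raw)
  out$p_adjusted[ok] <- holm_bonferroni(out$p_raw[ok])
  rownames(out) <- NULL
  out
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down familywise-error correction with monotonicity enforcement;
#' the output preserves the input order and never falls below the raw
#' p-values.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values.
#' @export
holm_bonferroni <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    abort_domain("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "holm")
}

#' Dichotomize risk scores at a percentile
#'
#' Patients whose risk strictly exceeds the q-quantile (linear-interpolation
#' definition) are labelled `high`; ties at the threshold fall to `low`.
#'
#' @param risk numeric risk scores (n >= 4).
#' @param q quantile fraction (default 0.75, the published split).
#' @return factor with levels `low`, `high`.
#' @export
percentile_risk_split <- function(risk, q = 0.75) {
  if (length(risk) < 4) abort_domain("need at least 4 risk scores")
  thr <- stats::quantile(risk, q, type = 7, names = FALSE)
  factor(ifelse(risk > thr, "high", "low"), levels = c("low", "high"))
}

#' Calibration of predicted survival at a horizon
#'
#' Patients are binned by quantiles of predicted survival; within each bin
#' the observed Kaplan-Meier survival at the horizon is compared with the
#' mean prediction. Bins emptied by ties are merged with their lower
#' neighbour.
#'
#' @param predicted predicted survival probabilities at `horizon`.
#' @param time observed times.
#' @param event event indicators.
#' @param horizon months.
#' @param n_bins number of quantile bins (default 5).
#' @return `data.frame` with `bin`, `n`, `predicted` (bin mean), `observed`
#'   (bin KM at horizon).
#' @export
calibration_table <- function(predicted, time, event, horizon, n_bins = 5) {
  if (horizon > max(time)) abort_domain("horizon beyond follow-up")
  br <- unique(stats::quantile(predicted, seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) br <- c(min(predicted) - 1e-9, max(predicted) + 1e-9)
  bin <- cut(predicted, breaks = br, include.lowest = TRUE)
  levs <- levels(droplevels(bin))
  rows <- lapply(seq_along(levs), function(i) {
    sel <- bin == levs[i]
    data.frame(bin = i, n = sum(sel), predicted = mean(predicted[sel]),
               observed = km_surv_at(time[sel], event[sel], horizon))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Recalibrate predicted survival by a complementary log-log shift
#'
#' Fits a one-parameter intercept update on the cloglog scale: predictions
#' are raised to a common power `exp(delta)` (equivalently, `log(-log S)`
#' is shifted by `delta`) where `delta` is chosen so the mean recalibrated
#' prediction matches the observed marginal Kaplan-Meier survival at the
#' horizon. Predictions are clipped to `[1e-6, 1 - 1e-6]` before the
#' transform, so the output always stays in `[0, 1]`.
#'
#' @param predicted predicted survival probabilities at `horizon`.
#' @param time observed times.
#' @param event event indicators.
#' @param horizon months.
#' @return list with `adjusted` (recalibrated predictions) and `shift`
#'   (the fitted cloglog intercept delta).
#' @export
recalibrate <- function(predicted, time, event, horizon) {
  p <- pmin(pmax(predicted, 1e-6), 1 - 1e-6)
  target <- km_surv_at(time, event, horizon)
  target <- pmin(pmax(target, 1e-6), 1 - 1e-6)
  f <- function(delta) mean(p^exp(delta)) - target
  sol <- stats::uniroot(f, c(-10, 10), tol = 1e-10)
  list(adjusted = p^exp(sol$root), shift = sol$root)
}
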