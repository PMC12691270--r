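test_that("Kaplan-Meier matches hand-computed product limits", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$survival, c(2 / 3, 2 / 3, 0), tolerance = 1e-12)
  km3 <- km_estimate(c(4, 5, 6), c(0, 0, 0))
  expect_true(all(km3$survival == 1))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM equals the empirical survival under no censoring and is a
           proper non-increasing curve", {
  set.seed(51)
  t <- rexp(200)
  km <- km_estimate(t, rep(1, 200))
  emp <- vapply(km$time, function(x) mean(t > x), numeric(1))
  expect_equal(km$survival, emp, tolerance = 1e-12)
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
})

test_that("two-group log-rank equals the hand O-E computation", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 0, 1, 1, 1)
  grp <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  res <- logrank_test(grp, time, event)
  expect_equal(res$statistic, hand_logrank(time, event, grp),
               tolerance = 1e-10)
  set.seed(52)
  for (rep in 1:10) {
    n <- 20
    time <- sample(1:15, n, replace = TRUE)
    event <- rbinom(n, 1, 0.8)
    grp <- rbinom(n, 1, 0.5) == 1
    if (length(unique(grp)) < 2 || sum(event) == 0) next
    expect_equal(logrank_test(grp, time, event)$statistic,
                 hand_logrank(time, event, grp), tolerance = 1e-10)
  }
})

test_that("log-rank is symmetric in labels and null on identical groups", {
  time <- rep(c(1, 2, 3, 5, 8), 2)
  event <- rep(c(1, 1, 0, 1, 1), 2)
  grp <- rep(c("a", "b"), each = 5)
  res <- logrank_test(grp, time, event)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
  swapped <- logrank_test(rev(grp), time, event)
  expect_equal(swapped$statistic, res$statistic, tolerance = 1e-12)
  expect_error(logrank_test(rep("a", 10), time, event), "2 non-empty")
})

test_that("log-rank type-I error is nominal under the null", {
  set.seed(53)
  rej <- mean(replicate(1000, {
    time <- rexp(100, 0.05)
    cens <- rexp(100, 0.02)
    obs <- pmin(time, cens)
    event <- as.integer(time <= cens)
    grp <- rep(c(0, 1), 50)
    logrank_test(grp, obs, event)$p < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("pairwise Cox recovers a planted hazard ratio of 2", {
  set.seed(54)
  n <- 4000
  grp <- rep(c("A", "B"), each = n / 2)
  rate <- ifelse(grp == "B", 0.06, 0.03)
  time <- rexp(n, rate)
  cens <- pmin(rexp(n, 0.02), 60)
  obs <- pmin(time, cens)
  event <- as.integer(time <= cens)
  hr <- cox_pairwise_hr(grp, obs, event)
  expect_equal(nrow(hr), 1)
  expect_gt(hr$hr, 1.8)
  expect_lt(hr$hr, 2.2)
  expect_true(hr$ci_low <= hr$hr && hr$hr <= hr$ci_high)
})

test_that("pairwise Cox on identical groups is null and three groups give
           three comparisons", {
  set.seed(55)
  n <- 1000
  time <- rexp(n, 0.05)
  event <- rbinom(n, 1, 0.8)
  grp2 <- rep(c("A", "B"), n / 2)
  hr <- cox_pairwise_hr(grp2, time, event)
  expect_gt(hr$hr, 0.8)
  expect_lt(hr$hr, 1.25)
  expect_gt(hr$p_raw, 0.05)
  grp3 <- rep(c("1", "2", "3"), length.out = n)
  hr3 <- cox_pairwise_hr(grp3, time, event)
  expect_equal(nrow(hr3), 3)
  expect_setequal(hr3$comparison, c("2 vs 1", "3 vs 1", "3 vs 2"))
  expect_true(all(hr3$p_adjusted >= hr3$p_raw))
})

test_that("a group without events is flagged, not dropped", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 0, 0, 0)
  grp <- rep(c("A", "B"), each = 3)
  hr <- cox_pairwise_hr(grp, time, event)
  expect_equal(nrow(hr), 1)
  expect_match(hr$flag, "no events")
  expect_true(is.na(hr$hr))
})

test_that("Holm-Bonferroni step-down matches the hand rule", {
  expect_equal(holm_bonferroni(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holm_bonferroni(0.2), 0.2)
  expect_equal(holm_bonferroni(c(1, 1)), c(1, 1))
  p <- c(0.04, 0.001, 0.3, 0.02)
  adj <- holm_bonferroni(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("percentile risk split follows the strict-inequality quantile rule", {
  s <- percentile_risk_split(1:100, q = 0.75)
  expect_equal(sum(s == "high"), 25)
  expect_equal(sum(percentile_risk_split(rep(3, 10)) == "high"), 0)
  s0 <- percentile_risk_split(c(1, 1, 2, 3, 4), q = 0)
  expect_equal(as.vector(table(s0)), c(2, 3)) # minima stay low
})

test_that("calibration table recovers true survival and exposes
           miscalibration", {
  set.seed(56)
  n <- 4000
  rate <- runif(n, 0.01, 0.08)
  time <- rexp(n, rate)
  cens <- rexp(n, 0.01)
  obs <- pmin(time, cens)
  event <- as.integer(time <= cens)
  pred <- exp(-rate * 24) # the true 24-month survival
  cal <- calibration_table(pred, obs, event, horizon = 24)
  expect_equal(nrow(cal), 5)
  expect_lt(max(abs(cal$predicted - cal$observed)), 0.05)
  expect_equal(sum(cal$n), n)
  # constant pessimistic predictions: single bin exposing the gap
  t2 <- rexp(500, 0.004)
  cal2 <- calibration_table(rep(0.5, 500), t2, rep(1, 500), horizon = 24,
                            n_bins = 5)
  expect_equal(nrow(cal2), 1)
  expect_gt(cal2$observed, 0.85)
  cal3 <- calibration_table(pred, obs, event, horizon = 24, n_bins = 1)
  expect_equal(nrow(cal3), 1)
  expect_equal(cal3$observed, km_surv_at_test(obs, event, 24),
               tolerance = 1e-12)
})

test_that("recalibration recovers a constructed cloglog shift", {
  set.seed(57)
  n <- 3000
  rate <- runif(n, 0.01, 0.05)
  time <- rexp(n, rate)
  obs <- pmin(time, 84)
  event <- as.integer(time <= 84)
  true_surv <- exp(-rate * 24)
  # already calibrated: shift near zero
  r0 <- recalibrate(true_surv, obs, event, horizon = 24)
  expect_lt(abs(r0$shift), 0.05)
  # miscalibrate by a known cloglog shift of +0.5 (too pessimistic)
  bad <- true_surv^exp(0.5)
  r1 <- recalibrate(bad, obs, event, horizon = 24)
  expect_lt(abs(r1$shift - (-0.5)) / 0.5, 0.10)
  expect_true(all(r1$adjusted >= 0 & r1$adjusted <= 1))
})
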