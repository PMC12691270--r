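make_grouped_cohort <- function(n_per, surv_rates, seed = 1) {
  # one categorical covariate "leafvar" with a distinct exponential
  # hazard per level; handy for exercising tree growth and merging
  set.seed(seed)
  k <- length(surv_rates)
  lab <- factor(rep(letters[1:k], each = n_per), levels = letters[1:k])
  time <- rexp(n_per * k, rep(surv_rates, each = n_per))
  cens <- rexp(n_per * k, 0.01)
  data.frame(id = as.character(seq_len(n_per * k)),
             leafvar = lab,
             time = pmin(time, cens),
             event = as.integer(time <= cens))
}

make_grid_cohort <- function(n_per, rates, seed = 1) {
  # two binary covariates, one exponential hazard per combination
  # (xp, xq, yp, yq); each tree path can then test both variables and
  # reach four leaves
  set.seed(seed)
  f1 <- factor(rep(c("x", "y"), each = 2 * n_per))
  f2 <- factor(rep(c("p", "q", "p", "q"), each = n_per))
  rate <- rates[2 * (f1 == "y") + (f2 == "q") + 1]
  time <- rexp(4 * n_per, rate)
  cens <- rexp(4 * n_per, 0.01)
  data.frame(id = as.character(seq_len(4 * n_per)), f1 = f1, f2 = f2,
             time = pmin(time, cens), event = as.integer(time <= cens))
}

test_that("discretization conventions: boundary to upper except KPS", {
  co <- data.frame(id = c("a", "b", "c", "d"),
                   siri = c(3.5, 3.49, 0.2, NA),
                   kps = c(70, 80, 100, 60),
                   bmi = c(25, 24.9, 30, 17))
  d <- discretize_cohort(co, list(siri = 3.5, kps = 70, bmi = c(25, 30)))
  expect_equal(as.character(d$siri), c("high", "low", "low", NA))
  expect_equal(as.character(d$kps), c("low", "high", "high", "low"))
  expect_equal(as.character(d$bmi), c("[25,30)", "<25", ">=30", "<25"))
  # empty cutoff set passes the column through
  d2 <- discretize_cohort(co, list(siri = numeric(0)))
  expect_identical(d2$siri, co$siri)
})

test_that("a strong binary effect grows a depth-1 tree with compliant
           leaves", {
  co <- make_grouped_cohort(200, c(0.01, 0.06), seed = 71)
  tree <- grow_risk_tree(co, "leafvar")
  expect_equal(tree_depth(tree), 1)
  expect_equal(nrow(tree$leaves), 2)
  expect_true(all(tree$leaves$n >= 40))
  # worse-survival level is group 2
  g <- assign_groups(tree, co)
  expect_equal(as.vector(tapply(g, co$leafvar, unique)), c(1, 2))
})

test_that("all-noise covariates mostly yield a single leaf", {
  set.seed(72)
  singles <- sum(replicate(20, {
    n <- 500
    co <- data.frame(id = as.character(1:n),
                     a = factor(sample(c("x", "y"), n, TRUE)),
                     b = factor(sample(c("p", "q", "r"), n, TRUE)))
    co$time <- rexp(n, 0.04)
    co$event <- as.integer(runif(n) < 0.7)
    tree <- grow_risk_tree(co, c("a", "b"))
    nrow(tree$leaves) == 1
  }))
  expect_gte(singles, 16)
})

test_that("grown trees always respect depth and node-size limits", {
  fx <- fitted_fixture()
  cuts <- list(siri = discover_cutoffs(fx$model, fx$train, "siri"),
               kps = discover_cutoffs(fx$model, fx$train, "kps"))
  tr_d <- discretize_cohort(fx$train, cuts)
  covs <- names(Filter(is.factor, tr_d[c("siri", "kps", "smoking")]))
  tree <- grow_risk_tree(tr_d, covs)
  expect_lte(tree_depth(tree), 3)
  expect_true(all(tree$leaves$n >= 40))
  # below 2 * min_node: trivial single leaf
  small <- tr_d[1:70, ]
  t_small <- grow_risk_tree(small, covs)
  expect_equal(nrow(t_small$leaves), 1)
})

test_that("leaf merging follows the minimal-log-rank adjacent rule,
           reproduced by an independent step-by-step oracle", {
  co <- make_grid_cohort(100, c(0.01, 0.012, 0.05, 0.055), seed = 73)
  tree <- grow_risk_tree(co, c("f1", "f2"), min_stat = 0.0, min_node = 40)
  expect_gte(nrow(tree$leaves), 3)
  merged <- merge_leaves(tree, co, n_groups = 3)
  expect_equal(sort(unique(merged$leaves$group)), 1:3)
  # independent oracle: order leaves by KM at 24 months, then repeatedly
  # merge the adjacent pair with the smallest hand-computed log-rank stat
  leaf_ids <- siristrat:::route_leaf(tree$root, co)
  lv <- tree$leaves
  ord <- order(-lv$surv, lv$leaf)
  blocks <- as.list(lv$leaf[ord])
  while (length(blocks) > 3) {
    stats <- sapply(seq_len(length(blocks) - 1), function(i) {
      sel <- leaf_ids %in% c(blocks[[i]], blocks[[i + 1]])
      hand_logrank(co$time[sel], co$event[sel],
                   leaf_ids[sel] %in% blocks[[i + 1]])
    })
    i <- which.min(stats)
    blocks[[i]] <- c(blocks[[i]], blocks[[i + 1]])
    blocks[[i + 1]] <- NULL
  }
  oracle_group <- integer(nrow(lv))
  for (g in seq_along(blocks)) oracle_group[lv$leaf %in% blocks[[g]]] <- g
  expect_equal(merged$leaves$group, oracle_group)
})

test_that("well-separated clusters merge to the best contiguous partition", {
  # survival roughly 0.9 / 0.85 / 0.5 / 0.45: expect {1,2} vs {3} vs {4}
  # or {1} {2} {3,4}; crucially the two good and the two poor leaves are
  # never split across non-adjacent groups
  co <- make_grid_cohort(120, c(0.004, 0.005, 0.028, 0.033), seed = 74)
  tree <- grow_risk_tree(co, c("f1", "f2"), min_stat = 0.0, min_node = 40)
  merged <- merge_leaves(tree, co, n_groups = 3)
  g <- assign_groups(merged, co)
  combo <- interaction(co$f1, co$f2, lex.order = TRUE)
  by_level <- as.vector(tapply(g, combo, unique))
  # the two low-hazard combinations (f1 = x) are merged into group 1 and
  # the two high-hazard ones split groups 2/3 by their observed survival
  expect_equal(by_level[1:2], c(1, 1))
  expect_setequal(by_level[3:4], c(2, 3))
  s24 <- sapply(3:4, function(i)
    km_surv_at_test(co$time[combo == levels(combo)[i]],
                    co$event[combo == levels(combo)[i]], 24))
  expect_equal(order(-s24) + 1, by_level[3:4])
  # n_groups equal to leaf count is the identity
  same <- merge_leaves(tree, co, n_groups = nrow(tree$leaves))
  expect_equal(sort(unique(same$leaves$group)), seq_len(nrow(tree$leaves)))
})

test_that("group ordering is monotone in training KM at the ranking
           horizon", {
  co <- make_grid_cohort(110, c(0.006, 0.015, 0.03, 0.06), seed = 75)
  tree <- grow_risk_tree(co, c("f1", "f2"), min_stat = 0.0)
  merged <- merge_leaves(tree, co, 3)
  g <- assign_groups(merged, co)
  surv24 <- sapply(sort(unique(g)), function(k)
    km_surv_at_test(co$time[g == k], co$event[g == k], 24))
  expect_true(all(diff(surv24) <= 1e-12))
})

test_that("the reference tree reproduces the published three-variable rule", {
  tree <- parsimonious_reference_tree()
  pts <- data.frame(
    id = as.character(1:6),
    siri = c(5.0, 1.0, 1.0, 1.0, 3.5, 1.0),
    kps = c(100, 60, 90, 90, 90, 70),
    smoking = factor(c("never", "never", "former", "never", "current",
                       "current"),
                     levels = c("never", "former", "current")))
  g <- assign_groups(tree, pts)
  # high SIRI -> worst regardless; low SIRI + low KPS -> worst;
  # low SIRI + high KPS split by smoking history
  expect_equal(g, c(3L, 3L, 2L, 1L, 3L, 3L))
  expect_lte(tree_depth(tree), 3)
  rules <- tree_rules(tree)
  expect_length(rules, 4)
})

test_that("reference-tree assignment equals the generator's planted truth", {
  sim <- simulate_cohort(500, 77, spec = covariate_spec(missing_rate = 0))
  tree <- parsimonious_reference_tree()
  g <- assign_groups(tree, sim$cohort)
  expect_identical(g, sim$truth$group)
})

test_that("assignment handles the empty cohort and reports missing
           covariates by patient", {
  tree <- parsimonious_reference_tree()
  empty <- data.frame(id = character(), siri = numeric(), kps = numeric(),
                      smoking = factor(character(),
                                       levels = c("never", "former",
                                                  "current")))
  expect_length(assign_groups(tree, empty), 0)
  bad <- data.frame(id = c("Pa", "Pb"), siri = c(1, 1), kps = c(NA, 90),
                    smoking = factor(c("never", "never"),
                                     levels = c("never", "former",
                                                "current")))
  expect_error(assign_groups(tree, bad), "Pa")
})

test_that("risk trees serialize to JSON and render as rules", {
  tree <- parsimonious_reference_tree()
  f <- tempfile(fileext = ".json")
  tree_to_json(tree, f)
  back <- jsonlite::fromJSON(f)
  expect_equal(back$max_depth, 3)
  expect_equal(nrow(back$leaves), 4)
  expect_match(tree_rules(tree)[4], "siri >= 3.5")
})
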