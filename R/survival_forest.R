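#' Fit a random survival forest
#'
#' Wraps a log-rank-splitting survival forest (backend: \pkg{ranger}) with
#' the settings fixed by this package: 1000 trees by default,
#' `mtry = ceiling(sqrt(p))`, minimum terminal node size 15, no depth limit.
#' At fit time every tree's internal structure is retained and the number of
#' training subjects reaching each node is recorded, so that all splitting
#' rules can later be harvested for cutoff discovery.
#'
#' @param train a cohort `data.frame` with complete covariates and fully
#'   observed `time`/`event` (at least 2 events).
#' @param covariates character vector of covariate column names.
#' @param seed integer seed; fitting and prediction are deterministic.
#' @param n_trees number of trees (default 1000).
#' @return an object of class `rsf_model`.
#' @export
fit_rsf <- function(train, covariates = COVARIATE_COLS, seed = 1,
                    n_trees = 1000) {
  check_cohort(train, need_outcomes = TRUE)
  unknown <- setdiff(covariates, names(train))
  if (length(unknown))
    abort_domain(paste("unknown covariates:", paste(unknown, collapse = ", ")))
  if (sum(train$event) < 2)
    abort_domain("need at least 2 events to fit a survival forest")
  if (anyNA(train[covariates]))
    abort_domain("covariates must be complete (impute first)")
  x <- train[covariates]
  rf <- ranger::ranger(
    x = x, y = survival::Surv(train$time, train$event),
    num.trees = n_trees,
    mtry = ceiling(sqrt(length(covariates))),
    min.node.size = 15,
    splitrule = "logrank",
    respect.unordered.factors = "order",
    num.threads = 1, seed = derive_seed(seed, 505L))
  model <- structure(
    list(ranger = rf, covariates = covariates,
         continuous = covariates[vapply(x, is.numeric, logical(1))],
         train_range = lapply(x[vapply(x, is.numeric, logical(1))], range),
         n_trees = n_trees, seed = seed),
    class = "rsf_model")
  model$node_sizes <- .node_sizes(model, x)
  model
}

# training-subject count reaching every node of every tree: route the
# training set to terminal nodes, then aggregate upward (in ranger each
# child's ID exceeds its parent's, so a single descending pass suffices)
.node_sizes <- function(model, x) {
  fr <- model$ranger$forest
  tn <- stats::predict(model$ranger, x, type = "terminalNodes",
                       num.threads = 1)$predictions
  lapply(seq_len(fr$num.trees), function(k) {
    left <- fr$child.nodeIDs[[k]][[1]]
    right <- fr$child.nodeIDs[[k]][[2]]
    n_nodes <- length(left)
    size <- tabulate(tn[, k] + 1L, nbins = n_nodes)
    for (node in rev(seq_len(n_nodes))) {
      if (left[node] != 0 || right[node] != 0)
        size[node] <- size[left[node] + 1L] + size[right[node] + 1L]
    }
    size
  })
}

#' Ensemble risk score
#'
#' The scalar risk of a patient is the ensemble cumulative hazard summed
#' over the training event-time grid (higher = worse prognosis), the usual
#' ensemble mortality convention for survival forests.
#'
#' @param model an `rsf_model`.
#' @param data a cohort `data.frame` with the model's covariates, complete.
#' @return numeric risk vector, one value per row of `data`.
#' @export
predict_risk <- function(model, data) {
  stopifnot(inherits(model, "rsf_model"))
  if (anyNA(data[model$covariates]))
    abort_domain("covariates must be complete for risk prediction")
  p <- stats::predict(model$ranger, data[model$covariates], num.threads = 1)
  rowSums(p$chf)
}

#' Predicted survival probability at a horizon
#'
#' Ensemble survival function evaluated at the last grid time not exceeding
#' the horizon.
#'
#' @inheritParams predict_risk
#' @param horizon months.
#' @return numeric vector of survival probabilities.
#' @export
predict_survival <- function(model, data, horizon) {
  stopifnot(inherits(model, "rsf_model"))
  p <- stats::predict(model$ranger, data[model$covariates], num.threads = 1)
  grid <- model$ranger$unique.death.times
  j <- findInterval(horizon, grid)
  if (j == 0) rep(1, nrow(data)) else p$survival[, j]
}

#' Harrell's concordance index
#'
#' The proportion of concordant pairs among evaluable pairs. A pair is
#' evaluable iff the observed times differ and the subject with the shorter
#' time had the event; it is concordant iff that subject carries the higher
#' risk; ties in risk count 1/2. Tied observed times are never evaluable,
#' which makes the index antisymmetric: `C(risk) + C(-risk) = 1` whenever
#' there are no risk ties.
#'
#' @param risk numeric risk scores (higher = worse).
#' @param time observed times.
#' @param event event indicators (1 = event, 0 = censored).
#' @return concordance in `[0, 1]`.
#' @export
harrell_cindex <- function(risk, time, event) {
  n <- length(risk)
  if (length(time) != n || length(event) != n)
    abort_domain("risk, time, event must have equal length")
  conc <- 0; npairs <- 0
  for (i in which(event == 1)) {
    later <- time > time[i]
    m <- sum(later)
    if (m == 0) next
    npairs <- npairs + m
    conc <- conc + sum(risk[i] > risk[later]) + 0.5 * sum(risk[i] == risk[later])
  }
  if (npairs == 0)
    abort_domain("no evaluable pairs (all censored or all times tied)")
  conc / npairs
}

#' Permutation variable importance
#'
#' The drop in concordance when one covariate's values are randomly
#' shuffled: mean over repeats of (baseline C-index minus the C-index after
#' permuting the variable's column). Evaluated on a supplied (typically
#' held-out) data set.
#'
#' @param model an `rsf_model`.
#' @param data cohort `data.frame` with outcomes, used for evaluation.
#' @param variable covariate name to permute.
#' @param n_repeats number of permutations (default 10).
#' @param seed integer seed.
#' @param perm optional permutation generator `function(n)` returning an
#'   index vector; by default a uniform random shuffle. Supplying
#'   `seq_len` yields the identity permutation and hence a VIMP of exactly
#'   zero (useful for verification).
#' @return mean C-index drop (positive = variable carries signal).
#' @export
permutation_vimp <- function(model, data, variable, n_repeats = 10, seed = 1,
                             perm = NULL) {
  stopifnot(inherits(model, "rsf_model"))
  if (!variable %in% model$covariates)
    abort_domain(paste("variable not in model roster:", variable))
  check_cohort(data, need_outcomes = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 606L))
  if (is.null(perm)) perm <- function(n) sample.int(n)
  base_c <- harrell_cindex(predict_risk(model, data), data$time, data$event)
  drops <- vapply(seq_len(n_repeats), function(r) {
    shuffled <- data
    shuffled[[variable]] <- shuffled[[variable]][perm(nrow(data))]
    base_c - harrell_cindex(predict_risk(model, shuffled),
                            data$time, data$event)
  }, numeric(1))
  mean(drops)
}

#' Time-dependent cumulative/dynamic AUC
#'
#' For each horizon t, cases are subjects with an event by t and controls
#' are subjects still at risk beyond t; case/control ordering by the risk
#' score is weighted by inverse probability of censoring (Kaplan-Meier of
#' the censoring distribution).
#'
#' @param risk numeric risk scores (higher = worse).
#' @param time observed times.
#' @param event event indicators.
#' @param horizons months at which to evaluate; each must not exceed the
#'   largest observed time.
#' @return named numeric vector of AUCs, one per horizon.
#' @export
time_dependent_auc <- function(risk, time, event, horizons) {
  if (any(horizons > max(time)))
    abort_domain("horizon beyond last observed time")
  # Kaplan-Meier of the censoring distribution G(t)
  cf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- stats::stepfun(cf$time, c(1, cf$surv))
  Gminus <- function(t) G(t - 1e-9)
  out <- vapply(horizons, function(h) {
    case <- which(time <= h & event == 1)
    ctrl <- which(time > h)
    if (!length(case) || !length(ctrl))
      abort_domain(sprintf("no cases or no controls at horizon %g", h))
    w <- 1 / pmax(vapply(time[case], Gminus, numeric(1)), 1e-12)
    num <- 0
    for (k in seq_along(case)) {
      i <- case[k]
      num <- num + w[k] * (sum(risk[i] > risk[ctrl]) +
                             0.5 * sum(risk[i] == risk[ctrl]))
    }
    num / (sum(w) * length(ctrl))
  }, numeric(1))
  names(out) <- paste0("t", horizons)
  out
}

#' Extract all splitting rules for a continuous covariate
#'
#' Walks every tree of the forest and returns one row per internal node
#' that splits on the requested variable: the numeric threshold and the
#' number of training subjects reaching that node. The distribution of
#' these thresholds is the raw material of cutoff discovery.
#'
#' @param model an `rsf_model`.
#' @param variable continuous covariate name.
#' @return `data.frame` with columns `tree`, `node`, `threshold`,
#'   `node_size` (zero rows if the forest never splits on the variable).
#' @export
extract_split_rules <- function(model, variable) {
  stopifnot(inherits(model, "rsf_model"))
  if (!variable %in% model$covariates)
    abort_domain(paste("variable not in model roster:", variable))
  if (!variable %in% model$continuous)
    abort_domain(paste("variable is not continuous:", variable))
  fr <- model$ranger$forest
  vid <- match(variable, fr$independent.variable.names) - 1L # 0-based
  if (is.na(vid)) # in the roster but never entered the fitted forest
    return(data.frame(tree = integer(), node = integer(),
                      threshold = numeric(), node_size = integer()))
  res <- lapply(seq_len(fr$num.trees), function(k) {
    left <- fr$child.nodeIDs[[k]][[1]]
    right <- fr$child.nodeIDs[[k]][[2]]
    internal <- which(left != 0 | right != 0)
    hit <- internal[fr$split.varIDs[[k]][internal] == vid]
    if (!length(hit)) return(NULL)
    data.frame(tree = k, node = hit - 1L,
               threshold = fr$split.values[[k]][hit],
               node_size = model$node_sizes[[k]][hit])
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(tree = integer(), node = integer(),
                      threshold = numeric(), node_size = integer())
  rownames(out) <- NULL
  out
}
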