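#' Gaussian kernel density estimate with Silverman bandwidth
#'
#' Weighted Gaussian KDE evaluated on an equispaced grid. The bandwidth is
#' Silverman's rule-of-thumb computed on the (weighted) sample, with the
#' effective sample size `(sum w)^2 / sum(w^2)` replacing n when weights are
#' supplied. The grid spans `[min - bw, max + bw]` unless an explicit range
#' is given, and the density is renormalized so its trapezoid-rule integral
#' over the grid is exactly 1 (boundary kernels would otherwise leak mass
#' outside the grid).
#'
#' @param values numeric sample (at least 2 distinct values).
#' @param weights optional nonnegative weights, recycled/normalized
#'   internally; `NULL` means uniform.
#' @param grid_size number of grid points (default 512).
#' @param from,to optional grid range (both or neither).
#' @return an object of class `density_estimate` with fields `grid`,
#'   `density`, `bandwidth`.
#' @export
kde_estimate <- function(values, weights = NULL, grid_size = 512,
                         from = NULL, to = NULL) {
  values <- values[!is.na(values)]
  if (length(unique(values)) < 2)
    abort_domain("need at least 2 distinct values for a density estimate")
  if (is.null(weights)) weights <- rep(1, length(values))
  if (length(weights) != length(values) || any(weights < 0))
    abort_domain("weights must be nonnegative and match values in length")
  w <- weights / sum(weights)
  bw <- silverman_bw(values, w)
  if (is.null(from)) from <- min(values) - bw
  if (is.null(to)) to <- max(values) + bw
  d <- stats::density(values, bw = bw, kernel = "gaussian", weights = w,
                      from = from, to = to, n = grid_size)
  dens <- d$y / trapz(d$x, d$y)
  structure(list(grid = d$x, density = dens, bandwidth = bw),
            class = "density_estimate")
}

# Silverman's rule on a weighted sample; errors when the spread is zero
silverman_bw <- function(values, w) {
  mu <- sum(w * values)
  sdw <- sqrt(sum(w * (values - mu)^2))
  qs <- weighted_quantile(values, w, c(0.25, 0.75))
  iqr <- qs[2] - qs[1]
  spread <- min(sdw, if (iqr > 0) iqr / 1.349 else Inf)
  if (!is.finite(spread) || spread <= 0)
    abort_domain("sample spread is zero; bandwidth undefined")
  n_eff <- 1 / sum(w^2)
  0.9 * spread * n_eff^(-1 / 5)
}

# weighted quantile by inverting the step CDF (left-continuous convention)
weighted_quantile <- function(values, w, probs) {
  o <- order(values)
  cw <- cumsum(w[o])
  vapply(probs, function(p) values[o][which(cw >= p * cw[length(cw)])[1]],
         numeric(1))
}

# trapezoid-rule integral on an ordered grid
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Local maxima of the density difference
#'
#' Computes `d = split_density - data_density` on the split density's grid
#' (the data density is linearly interpolated onto it when the grids differ)
#' and returns the grid points that are strict local maxima of `d` with
#' `d > 0`. Plateau maxima resolve to their leftmost grid point; boundary
#' grid points are never maxima. These are the candidate cutoffs: covariate
#' values where the forest splits more often than the covariate's own mass
#' would explain.
#'
#' Because a forest splitting at random produces a threshold distribution
#' that only roughly tracks the covariate distribution, the difference
#' always shows shallow positive pockets; a strict `d > 0` rule would
#' therefore manufacture cutoffs out of noise. A maximum is only kept where
#' the split density exceeds `min_ratio` times the data density — i.e.
#' where the forest splits at least that many times more densely than the
#' covariate's own mass explains. Under a signal-free forest this relative
#' excess stays below about 2, while a genuine threshold effect
#' concentrates splits severalfold above the background, so the default of
#' 2 separates the regimes.
#'
#' @param split_density `density_estimate` of the forest's split thresholds.
#' @param data_density `density_estimate` of the covariate in the training
#'   data.
#' @param min_ratio minimum split/data density ratio at a retained maximum
#'   (default 2; set to 0 to disable the guard).
#' @return `data.frame` with columns `cutoff` and `score` (the difference
#'   height), ordered by decreasing score.
#' @export
density_difference_maxima <- function(split_density, data_density,
                                      min_ratio = 2) {
  stopifnot(inherits(split_density, "density_estimate"),
            inherits(data_density, "density_estimate"))
  grid <- split_density$grid
  if (length(data_density$grid) == length(grid) &&
      max(abs(data_density$grid - grid)) < 1e-9) {
    g <- data_density$density
  } else {
    g <- stats::approx(data_density$grid, data_density$density, xout = grid,
                       yleft = 0, yright = 0)$y
  }
  d <- split_density$density - g
  n <- length(d)
  # collapse plateaus, then test strict rise/fall around each run
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  keep <- logical(k)
  for (j in seq_len(k)) {
    if (starts[j] == 1L || ends[j] == n) next # boundary runs are never maxima
    keep[j] <- r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L] &&
      r$values[j] > 0
  }
  idx <- starts[keep] # leftmost point of each maximal run
  if (min_ratio > 0 && length(idx)) {
    rel <- split_density$density[idx] >= min_ratio * g[idx]
    idx <- idx[rel]
  }
  out <- data.frame(cutoff = grid[idx], score = d[idx])
  rownames(out) <- NULL
  out[order(-out$score), , drop = FALSE]
}

#' Exclude cutoffs that create minor groups
#'
#' Candidates are processed greedily in decreasing score order; a cutoff is
#' accepted only if every interval of the partition induced by the cutoffs
#' accepted so far (including the candidate) retains at least `min_prop` of
#' the training values. The convention `value >= cutoff` assigns values to
#' the upper interval. Rejected candidates are recorded with the reason.
#'
#' @param candidates `data.frame` with `cutoff` and `score` columns (as
#'   returned by [density_difference_maxima()]).
#' @param training_values numeric covariate values in the training data.
#' @param min_prop minimum fraction of training values per interval
#'   (default 0.10).
#' @param variable covariate name recorded in the result.
#' @return an object of class `cutoff_set` with fields `variable`,
#'   `cutoffs` (increasing), `scores` (aligned), `excluded` (data.frame with
#'   reasons), `parameters`.
#' @export
filter_minor_groups <- function(candidates, training_values, min_prop = 0.10,
                                variable = NA_character_) {
  training_values <- training_values[!is.na(training_values)]
  accepted <- numeric(0); acc_score <- numeric(0)
  excluded <- data.frame(cutoff = numeric(0), score = numeric(0),
                         reason = character(0))
  ord <- order(-candidates$score)
  for (j in ord) {
    cand <- candidates$cutoff[j]
    trial <- sort(c(accepted, cand))
    prop <- tabulate(findInterval(training_values, trial) + 1L,
                     nbins = length(trial) + 1L) / length(training_values)
    if (all(prop >= min_prop)) {
      accepted <- trial
      acc_score <- append(acc_score, candidates$score[j],
                          after = match(cand, trial) - 1L)
    } else {
      excluded <- rbind(excluded, data.frame(
        cutoff = cand, score = candidates$score[j],
        reason = sprintf("interval below %.0f%% occupancy", 100 * min_prop)))
    }
  }
  structure(list(variable = variable, cutoffs = accepted, scores = acc_score,
                 excluded = excluded,
                 parameters = list(min_prop = min_prop)),
            class = "cutoff_set")
}

#' Discover robust cutoffs for a continuous covariate from a fitted forest
#'
#' The package's central algorithm. All splitting rules involving the
#' covariate are harvested from the forest; the density of their thresholds
#' is estimated by a Gaussian KDE (by default weighting each rule by the
#' number of training subjects at its node) and compared against the KDE of
#' the covariate in the training data, both evaluated on one common grid.
#' Cutoffs are the strict local maxima of the density difference, filtered
#' by the minor-group occupancy rule. The result is deterministic given the
#' fitted model.
#'
#' @param model an `rsf_model` fitted on `train`.
#' @param train the training cohort.
#' @param variable continuous covariate name.
#' @param weighted weight split rules by node size (default `TRUE`); set
#'   `FALSE` to count each extracted rule once.
#' @param min_prop minor-group exclusion threshold (default 0.10).
#' @param min_ratio relative-excess guard for candidate maxima, see
#'   [density_difference_maxima()].
#' @param grid_size KDE grid resolution (default 512).
#' @return a `cutoff_set`; when the forest never splits on the variable the
#'   set is empty and carries `diagnostic = "never_split"`.
#' @export
discover_cutoffs <- function(model, train, variable, weighted = TRUE,
                             min_prop = 0.10, min_ratio = 2,
                             grid_size = 512) {
  rules <- extract_split_rules(model, variable)
  empty <- function(diag) structure(
    list(variable = variable, cutoffs = numeric(0), scores = numeric(0),
         excluded = data.frame(cutoff = numeric(0), score = numeric(0),
                               reason = character(0)),
         parameters = list(min_prop = min_prop, weighted = weighted,
                           min_ratio = min_ratio),
         diagnostic = diag),
    class = "cutoff_set")
  if (nrow(rules) == 0) return(empty("never_split"))
  if (length(unique(rules$threshold)) < 2) return(empty("degenerate_thresholds"))
  x <- train[[variable]]
  x <- x[!is.na(x)]
  w <- if (weighted) rules$node_size else NULL
  bw_s <- silverman_bw(rules$threshold,
                       if (is.null(w)) rep(1 / nrow(rules), nrow(rules))
                       else w / sum(w))
  bw_d <- silverman_bw(x, rep(1 / length(x), length(x)))
  lo <- min(rules$threshold, x) - max(bw_s, bw_d)
  hi <- max(rules$threshold, x) + max(bw_s, bw_d)
  f_split <- kde_estimate(rules$threshold, weights = w, grid_size = grid_size,
                          from = lo, to = hi)
  f_data <- kde_estimate(x, grid_size = grid_size, from = lo, to = hi)
  cand <- density_difference_maxima(f_split, f_data, min_ratio = min_ratio)
  out <- filter_minor_groups(cand, x, min_prop = min_prop, variable = variable)
  out$parameters$weighted <- weighted
  out$parameters$min_ratio <- min_ratio
  out$parameters$bandwidth_split <- f_split$bandwidth
  out$parameters$bandwidth_data <- f_data$bandwidth
  out
}

#' Serialize a cutoff set to JSON
#'
#' @param cs a `cutoff_set`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @export
cutoffs_to_json <- function(cs, path = NULL) {
  stopifnot(inherits(cs, "cutoff_set"))
  obj <- list(variable = cs$variable, cutoffs = cs$cutoffs, scores = cs$scores,
              excluded = cs$excluded, parameters = cs$parameters)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat(sprintf("Cutoff set for '%s': %d retained, %d excluded\n",
              x$variable, length(x$cutoffs), nrow(x$excluded)))
  if (length(x$cutoffs))
    cat("  cutoffs:", paste(sprintf("%.3f", x$cutoffs), collapse = ", "), "\n")
  invisible(x)
}
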