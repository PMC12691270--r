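#' Discretize continuous covariates at discovered cutoffs
#'
#' Each continuous covariate with a non-empty cutoff set is replaced by an
#' interval factor. The default boundary convention sends `value >= cutoff`
#' to the upper interval (so SIRI 3.5 at cutoff 3.5 is "high"); for
#' variables named in `lower_inclusive` the boundary itself belongs to the
#' lower interval (`value <= cutoff` is low), matching the KPS reporting
#' band convention where KPS = 70 falls in the 70-40 band.
#'
#' @param cohort a cohort `data.frame`.
#' @param cutoffs named list: variable name -> `cutoff_set` or numeric
#'   cutoff vector. Variables without cutoffs pass through untouched.
#' @param lower_inclusive character vector of variables using the
#'   boundary-to-lower convention (default `"kps"`).
#' @return the cohort with listed continuous columns replaced by ordered
#'   factors; a single cutoff yields levels `low`/`high`, several yield
#'   interval labels. Missing values stay missing.
#' @export
discretize_cohort <- function(cohort, cutoffs, lower_inclusive = "kps") {
  for (var in names(cutoffs)) {
    cs <- cutoffs[[var]]
    cuts <- if (inherits(cs, "cutoff_set")) cs$cutoffs else as.numeric(cs)
    if (!length(cuts)) next
    if (!var %in% names(cohort)) abort_domain(paste("no column", var))
    x <- cohort[[var]]
    if (!is.numeric(x)) next
    cuts <- sort(cuts)
    lower <- var %in% lower_inclusive
    # bin index = number of cutoffs at or below x (upper convention) or
    # strictly below x (lower-inclusive convention)
    bin <- if (lower) findInterval(x, cuts, left.open = TRUE)
           else findInterval(x, cuts)
    labs <- interval_labels(cuts, lower)
    cohort[[var]] <- factor(labs[bin + 1L], levels = labs, ordered = TRUE)
  }
  cohort
}

interval_labels <- function(cuts, lower_inclusive) {
  k <- length(cuts)
  if (k == 1) return(c("low", "high"))
  lo <- c(-Inf, cuts); hi <- c(cuts, Inf)
  br <- if (lower_inclusive) c("(", "]") else c("[", ")")
  vapply(seq_len(k + 1), function(i) {
    if (i == 1) sprintf("<%s%g", if (lower_inclusive) "=" else "", cuts[1])
    else if (i == k + 1) sprintf(">%s%g", if (lower_inclusive) "" else "=", cuts[k])
    else sprintf("%s%g,%g%s", br[1], lo[i], hi[i], br[2])
  }, character(1))
}

# --- internal node / tree representation -----------------------------------
# internal node: list(var, split, left, right); split is either
#   list(type = "levels", left_levels = <chr>)            (categorical) or
#   list(type = "threshold", value = <num>, op = ">=" | ">")  (right branch)
# leaf: list(leaf = <int>)

new_leaf <- function(id) list(leaf = id)
is_leaf <- function(node) !is.null(node$leaf)

# route rows of a cohort to leaf ids; errors when a needed covariate is
# missing, naming the patients
route_leaf <- function(node, cohort) {
  out <- integer(nrow(cohort))
  recur <- function(node, idx) {
    if (!length(idx)) return()
    if (is_leaf(node)) { out[idx] <<- node$leaf; return() }
    v <- cohort[[node$var]][idx]
    if (anyNA(v)) {
      ids <- if ("id" %in% names(cohort)) cohort$id[idx][is.na(v)]
             else idx[is.na(v)]
      abort_domain(paste0("missing '", node$var, "' for patient(s): ",
                          paste(ids, collapse = ", ")))
    }
    right <- if (node$split$type == "levels") {
      !(as.character(v) %in% node$split$left_levels)
    } else if (node$split$op == ">=") {
      v >= node$split$value
    } else {
      v > node$split$value
    }
    recur(node$left, idx[!right])
    recur(node$right, idx[right])
  }
  recur(node, seq_len(nrow(cohort)))
  out
}

km_surv_at <- function(time, event, horizon) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  j <- findInterval(horizon, sf$time)
  if (j == 0) 1 else sf$surv[j]
}

#' Grow a constrained survival decision tree on categorical covariates
#'
#' Recursive binary partitioning: at each node, every admissible binary
#' partition of every unused categorical covariate's levels is scored by
#' the two-group log-rank statistic, and the best split is taken. Ordered
#' factors (discretized continuous covariates) split only at thresholds,
#' i.e. into contiguous level blocks; nominal factors may split into any
#' two level subsets. Growth stops at the
#' depth limit, when a child would fall below the minimum node size, or when
#' the best statistic is below `min_stat` (3.84, the chi-square(1) critical
#' value at 0.05). Each root-to-leaf path tests a variable at most once.
#' Leaves are ordered by Kaplan-Meier survival at `horizon` and initially
#' labelled group 1 (best) to k (worst).
#'
#' @param train a discretized cohort with outcomes; all covariates factors.
#' @param covariates covariate names to consider.
#' @param max_depth maximum tree depth (default 3; root is depth 0).
#' @param min_node minimum subjects per leaf (default 40).
#' @param min_stat minimum log-rank statistic to accept a split
#'   (default 3.84).
#' @param horizon months at which leaves are ranked (default 24).
#' @return an object of class `risk_tree`.
#' @export
grow_risk_tree <- function(train, covariates, max_depth = 3, min_node = 40,
                           min_stat = 3.84, horizon = 24) {
  check_cohort(train, need_outcomes = TRUE)
  for (v in covariates)
    if (!is.factor(train[[v]]))
      abort_domain(paste("covariate must be categorical:", v))
  grow <- function(idx, depth, used) {
    if (depth >= max_depth || length(idx) < 2 * min_node)
      return(new_leaf(0L))
    best <- NULL
    for (v in setdiff(covariates, used)) {
      x <- droplevels(factor(train[[v]][idx],
                             ordered = is.ordered(train[[v]])))
      levs <- levels(x)
      if (length(levs) < 2) next
      # ordered factors split by threshold (contiguous prefixes);
      # nominal factors over all proper subsets up to complement symmetry
      subsets <- if (is.ordered(x)) {
        lapply(seq_len(length(levs) - 1), function(k) levs[seq_len(k)])
      } else {
        level_subsets(levs)
      }
      for (s in subsets) {
        left <- as.character(x) %in% s
        nl <- sum(left); nr <- length(idx) - nl
        if (nl < min_node || nr < min_node) next
        sd <- survival::survdiff(
          survival::Surv(train$time[idx], train$event[idx]) ~ left)
        if (is.null(best) || sd$chisq > best$stat + 1e-12)
          best <- list(stat = sd$chisq, var = v, left_levels = s)
      }
    }
    if (is.null(best) || best$stat < min_stat) return(new_leaf(0L))
    left <- as.character(train[[best$var]][idx]) %in% best$left_levels
    list(var = best$var,
         split = list(type = "levels", left_levels = best$left_levels),
         stat = best$stat,
         left = grow(idx[left], depth + 1, c(used, best$var)),
         right = grow(idx[!left], depth + 1, c(used, best$var)))
  }
  root <- grow(seq_len(nrow(train)), 0L, character(0))
  root <- number_leaves(root)
  tree <- structure(list(root = root, max_depth = max_depth,
                         min_node = min_node, horizon = horizon,
                         variables = covariates),
                    class = "risk_tree")
  leaf_ids <- route_leaf(root, train)
  tab <- sort(unique(leaf_ids))
  surv24 <- vapply(tab, function(l) {
    sel <- leaf_ids == l
    km_surv_at(train$time[sel], train$event[sel], horizon)
  }, numeric(1))
  n <- vapply(tab, function(l) sum(leaf_ids == l), integer(1))
  ord <- order(-surv24, tab) # best survival first; leaf index breaks ties
  leaves <- data.frame(leaf = tab, n = n, surv = surv24)
  leaves$group <- match(leaves$leaf, leaves$leaf[ord])
  tree$leaves <- leaves
  tree
}

# proper nonempty subsets of levs containing levs[1]
level_subsets <- function(levs) {
  rest <- levs[-1]
  subs <- list(levs[1])
  for (r in rest) subs <- c(subs, lapply(subs, c, r))
  subs[lengths(subs) < length(levs)]
}

number_leaves <- function(node) {
  counter <- 0L
  recur <- function(node) {
    if (is_leaf(node)) {
      counter <<- counter + 1L
      return(new_leaf(counter))
    }
    node$left <- recur(node$left)
    node$right <- recur(node$right)
    node
  }
  recur(node)
}

#' Merge tree leaves into ordered risk groups
#'
#' Leaves are ordered by training Kaplan-Meier survival at the tree's
#' ranking horizon; adjacent blocks are then merged iteratively, always
#' merging the pair with the smallest two-group log-rank statistic
#' (i.e. the most similar neighbouring survival curves), until `n_groups`
#' blocks remain. Groups are labelled 1 (best survival) to `n_groups`
#' (worst).
#'
#' @param tree a `risk_tree`.
#' @param train the training cohort the tree was grown on.
#' @param n_groups target number of risk groups (default 3).
#' @return the tree with its `leaves$group` mapping updated.
#' @export
merge_leaves <- function(tree, train, n_groups = 3) {
  stopifnot(inherits(tree, "risk_tree"))
  leaf_ids <- route_leaf(tree$root, train)
  lv <- tree$leaves
  if (nrow(lv) <= n_groups) {
    lv$group <- rank(-lv$surv, ties.method = "first")
    tree$leaves <- lv
    return(tree)
  }
  ord <- order(-lv$surv, lv$leaf) # best first
  blocks <- as.list(lv$leaf[ord])
  pair_stat <- function(a, b) {
    sel_a <- leaf_ids %in% a; sel_b <- leaf_ids %in% b
    sel <- sel_a | sel_b
    survival::survdiff(
      survival::Surv(train$time[sel], train$event[sel]) ~ sel_b[sel])$chisq
  }
  while (length(blocks) > n_groups) {
    stats <- vapply(seq_len(length(blocks) - 1), function(i)
      pair_stat(blocks[[i]], blocks[[i + 1]]), numeric(1))
    i <- which.min(stats) # leftmost minimum on ties
    blocks[[i]] <- c(blocks[[i]], blocks[[i + 1]])
    blocks[[i + 1]] <- NULL
  }
  for (g in seq_along(blocks))
    lv$group[lv$leaf %in% blocks[[g]]] <- g
  tree$leaves <- lv
  tree
}

#' The published parsimonious risk tree
#'
#' The fixed three-variable rule validated in oropharyngeal cancer:
#' SIRI >= 3.5 implies the worst group regardless of other covariates;
#' otherwise KPS <= 70 also implies the worst group; otherwise ever-smokers
#' (former or current) form the intermediate group and never-smokers the
#' best group. Encoded as a four-leaf tree whose two high-risk leaves share
#' group 3.
#'
#' @param threshold_siri,threshold_kps cutoffs (defaults 3.5 and 70).
#' @return a `risk_tree` operating on raw `siri`, `kps`, `smoking` columns.
#' @export
parsimonious_reference_tree <- function(threshold_siri = 3.5,
                                        threshold_kps = 70) {
  root <- list(
    var = "siri",
    split = list(type = "threshold", value = threshold_siri, op = ">="),
    left = list(
      var = "kps",
      split = list(type = "threshold", value = threshold_kps, op = ">"),
      # right branch: kps > threshold (good performance)
      right = list(
        var = "smoking",
        split = list(type = "levels", left_levels = "never"),
        left = new_leaf(1L),   # never-smoker
        right = new_leaf(2L)), # ever-smoker
      left = new_leaf(3L)),    # kps <= threshold
    right = new_leaf(4L))      # siri >= threshold
  leaves <- data.frame(leaf = 1:4, n = NA_integer_, surv = NA_real_,
                       group = c(1L, 2L, 3L, 3L))
  structure(list(root = root, max_depth = 3, min_node = 40, horizon = 24,
                 variables = c("siri", "kps", "smoking"), leaves = leaves,
                 reference = TRUE),
            class = "risk_tree")
}

#' Assign patients to risk groups
#'
#' Routes every patient down the tree and returns the group of the reached
#' leaf. A missing covariate on a needed path raises an error naming the
#' affected patients.
#'
#' @param tree a `risk_tree`.
#' @param cohort a cohort `data.frame`.
#' @return integer vector of groups (length `nrow(cohort)`; empty cohort
#'   yields an empty assignment).
#' @export
assign_groups <- function(tree, cohort) {
  stopifnot(inherits(tree, "risk_tree"))
  if (nrow(cohort) == 0) return(integer(0))
  leaf_ids <- route_leaf(tree$root, cohort)
  tree$leaves$group[match(leaf_ids, tree$leaves$leaf)]
}

#' Depth of a risk tree
#' @param tree a `risk_tree`.
#' @return integer depth (0 for a single leaf).
#' @export
tree_depth <- function(tree) {
  recur <- function(node) {
    if (is_leaf(node)) return(0L)
    1L + max(recur(node$left), recur(node$right))
  }
  recur(tree$root)
}

#' Render a risk tree as a plain-text rule list
#' @param tree a `risk_tree`.
#' @return character vector, one "IF ... THEN group g" rule per leaf.
#' @export
tree_rules <- function(tree) {
  rules <- character(0)
  recur <- function(node, conds) {
    if (is_leaf(node)) {
      g <- tree$leaves$group[tree$leaves$leaf == node$leaf]
      rules <<- c(rules, sprintf("IF %s THEN group %d",
                                 if (length(conds)) paste(conds, collapse = " AND ")
                                 else "TRUE", g))
      return()
    }
    s <- node$split
    if (s$type == "levels") {
      lc <- sprintf("%s in {%s}", node$var, paste(s$left_levels, collapse = ","))
      rc <- sprintf("%s not in {%s}", node$var, paste(s$left_levels, collapse = ","))
    } else {
      inv <- if (s$op == ">=") "<" else "<="
      lc <- sprintf("%s %s %g", node$var, inv, s$value)
      rc <- sprintf("%s %s %g", node$var, s$op, s$value)
    }
    recur(node$left, c(conds, lc))
    recur(node$right, c(conds, rc))
  }
  recur(tree$root, character(0))
  rules
}

#' Serialize a risk tree to JSON
#' @param tree a `risk_tree`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @export
tree_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "risk_tree"))
  obj <- list(root = tree$root, leaves = tree$leaves,
              max_depth = tree$max_depth, min_node = tree$min_node,
              variables = tree$variables)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @export
print.risk_tree <- function(x, ...) {
  cat(sprintf("Risk tree: depth %d, %d leaves, %d groups\n",
              tree_depth(x), nrow(x$leaves), length(unique(x$leaves$group))))
  cat(paste0("  ", tree_rules(x)), sep = "\n")
  invisible(x)
}
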