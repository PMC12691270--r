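#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end workflow with the defaults used
#' throughout the package: 1000-tree forest, depth-3 / node-40 risk tree,
#' 10 percent minor-group floor, 70/30 split, evaluation horizons 12-60
#' months. The configuration round-trips unchanged through
#' [write_config()] / [read_config()].
#'
#' @param seed global integer seed; all stage seeds derive from it.
#' @param n cohort size.
#' @param covariates covariate spec, see [covariate_spec()].
#' @param hazards hazard spec, see [hazard_spec()].
#' @param n_trees forest size.
#' @param max_depth,min_node,min_stat risk-tree constraints.
#' @param min_prop minor-group exclusion floor for cutoff discovery.
#' @param split_frac training fraction.
#' @param horizons evaluation horizons in months.
#' @param n_groups number of merged risk groups.
#' @param tree_covariates covariates offered to the risk tree. The default
#'   is the parsimonious roster (SIRI, performance status, smoking): the
#'   forest and cutoff discovery still see BMI, but the final tree is grown
#'   without it, mirroring the model simplification in which BMI was dropped
#'   before the final stratification.
#' @param smoking_binary recode smoking to never/ever for the tree stage
#'   (default `TRUE`, the parsimonious model's grouping of current and
#'   former smokers); the three-level variable is untouched elsewhere.
#' @param use_reference_tree skip discovery/growth and apply the published
#'   parsimonious tree instead.
#' @param out_dir optional output directory for artifacts.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n = 600,
                            covariates = covariate_spec(),
                            hazards = hazard_spec(),
                            n_trees = 1000,
                            max_depth = 3, min_node = 40, min_stat = 3.84,
                            min_prop = 0.10,
                            split_frac = 0.70,
                            horizons = seq(12, 60, by = 12),
                            n_groups = 3,
                            tree_covariates = c("siri", "kps", "smoking"),
                            smoking_binary = TRUE,
                            use_reference_tree = FALSE,
                            out_dir = NULL) {
  structure(list(seed = seed, n = n, covariates = covariates,
                 hazards = hazards, n_trees = n_trees, max_depth = max_depth,
                 min_node = min_node, min_stat = min_stat, min_prop = min_prop,
                 split_frac = split_frac, horizons = horizons,
                 n_groups = n_groups, tree_covariates = tree_covariates,
                 smoking_binary = smoking_binary,
                 use_reference_tree = use_reference_tree,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration (JSON)
#' @param config a `pipeline_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$covariates <- unclass(x$covariates)
  x$hazards <- unclass(x$hazards)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"))
  x$covariates <- do.call(covariate_spec, as.list(x$covariates))
  x$hazards <- do.call(hazard_spec, as.list(x$hazards))
  if (is.null(x$out_dir)) x["out_dir"] <- list(NULL)
  do.call(pipeline_config, x)
}

#' Simulate a cohort and split it, writing the stage artifacts
#'
#' Generates the synthetic cohort, splits it 70/30 before any modelling,
#' and (when `out_dir` is set) writes `train.csv`, `test.csv` and
#' `truth.csv` plus a log with the seed and content hashes.
#'
#' @param config a `pipeline_config`.
#' @return list with `train`, `test`, `truth_train`, `truth_test`.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$n < 2 * config$min_node)
    warning("cohort smaller than twice the minimum node size; ",
            "the risk tree will be a single leaf")
  sim <- simulate_cohort(config$n, config$seed, config$covariates,
                         config$hazards)
  part <- split_cohort(sim$cohort, config$seed, config$split_frac)
  out <- list(train = sim$cohort[part == "train_validation", ],
              test = sim$cohort[part == "test", ],
              truth_train = sim$truth[part == "train_validation", ],
              truth_test = sim$truth[part == "test", ])
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(config$out_dir))
      abort_domain(paste("cannot create output directory:", config$out_dir))
    paths <- c(train = file.path(config$out_dir, "train.csv"),
               test = file.path(config$out_dir, "test.csv"))
    write_cohort(out$train, paths["train"])
    write_cohort(out$test, paths["test"])
    truth <- rbind(out$truth_train, out$truth_test)
    utils::write.csv(truth, file.path(config$out_dir, "truth.csv"),
                     row.names = FALSE, na = "")
    log_stage(config$out_dir, "simulate",
              c(paths, truth = file.path(config$out_dir, "truth.csv")),
              config$seed)
  }
  out
}

log_stage <- function(out_dir, stage, paths, seed) {
  hashes <- tools::md5sum(paths)
  lines <- sprintf("%s\t%s\tseed=%s\t%s\t%s",
                   format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, seed,
                   names(paths), hashes)
  cat(lines, sep = "\n", file = file.path(out_dir, "pipeline.log"),
      append = TRUE)
  cat("\n", file = file.path(out_dir, "pipeline.log"), append = TRUE)
}

#' Run the full stratification pipeline
#'
#' simulate -> impute (within each partition) -> fit forest -> discover
#' cutoffs -> discretize -> grow tree -> merge leaves -> assign groups ->
#' evaluate. No test-set information enters any training stage: imputation
#' runs separately per partition and the forest, cutoffs and tree see only
#' the training partition.
#'
#' @param config a `pipeline_config`.
#' @return list with `config`, `model`, `cutoffs` (per continuous
#'   covariate), `tree`, `groups_test`, `report` (test-set statistics:
#'   C-index, log-rank, pairwise HRs, KM curves per group, calibration,
#'   75th-percentile risk split, agreement with the planted truth).
#' @export
run_full <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  data <- run_simulate(config)
  train <- rf_impute(data$train, seed = derive_seed(config$seed, 1L))
  test <- rf_impute(data$test, seed = derive_seed(config$seed, 2L))
  covs <- COVARIATE_COLS
  model <- fit_rsf(train, covs, seed = config$seed, n_trees = config$n_trees)
  risk_test <- predict_risk(model, test)
  cindex <- harrell_cindex(risk_test, test$time, test$event)

  if (config$use_reference_tree) {
    cutoffs <- NULL
    tree <- parsimonious_reference_tree(config$hazards$threshold_siri,
                                        config$hazards$threshold_kps)
    groups_train <- assign_groups(tree, train)
    groups_test <- assign_groups(tree, test)
  } else {
    continuous <- covs[vapply(train[covs], is.numeric, logical(1))]
    cutoffs <- lapply(continuous, function(v)
      discover_cutoffs(model, train, v, min_prop = config$min_prop))
    names(cutoffs) <- continuous
    train_d <- discretize_cohort(train, cutoffs)
    test_d <- discretize_cohort(test, cutoffs)
    if (isTRUE(config$smoking_binary)) {
      recode <- function(s) factor(ifelse(s == "never", "never", "ever"),
                                   levels = c("never", "ever"))
      train_d$smoking <- recode(train_d$smoking)
      test_d$smoking <- recode(test_d$smoking)
    }
    tree_covs <- intersect(config$tree_covariates, covs)
    tree_covs <- tree_covs[vapply(train_d[tree_covs], is.factor, logical(1))]
    tree <- grow_risk_tree(train_d, tree_covs, max_depth = config$max_depth,
                           min_node = config$min_node,
                           min_stat = config$min_stat)
    tree <- merge_leaves(tree, train_d, config$n_groups)
    groups_train <- assign_groups(tree, train_d)
    groups_test <- assign_groups(tree, test_d)
  }

  report <- evaluate_groups(groups_test, test, risk_test, model,
                            config$horizons)
  report$km_train <- lapply(split(seq_along(groups_train), groups_train),
                            function(i) km_estimate(train$time[i],
                                                    train$event[i]))
  if (!is.null(data$truth_test$group))
    report$truth_agreement <- mean(groups_test == data$truth_test$group)

  if (!is.null(config$out_dir)) {
    if (!is.null(cutoffs))
      for (v in names(cutoffs))
        cutoffs_to_json(cutoffs[[v]],
                        file.path(config$out_dir, paste0("cutoffs_", v, ".json")))
    tree_to_json(tree, file.path(config$out_dir, "risk_tree.json"))
    report_path <- file.path(config$out_dir, "report.json")
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                                null = "null", dataframe = "rows",
                                force = TRUE, pretty = TRUE), report_path)
    log_stage(config$out_dir, "full",
              c(report = report_path), config$seed)
  }
  list(config = config, model = model, cutoffs = cutoffs, tree = tree,
       groups_test = groups_test, report = report)
}

# test-set stratification statistics shared by the pipeline paths
evaluate_groups <- function(groups, test, risk, model, horizons) {
  groups_f <- factor(groups)
  report <- list(cindex = harrell_cindex(risk, test$time, test$event))
  if (nlevels(droplevels(groups_f)) >= 2) {
    lr <- logrank_test(groups_f, test$time, test$event)
    report$logrank <- lr
    report$pairwise_hr <- cox_pairwise_hr(groups_f, test$time, test$event)
  }
  report$km <- lapply(split(seq_along(groups), groups),
                      function(i) km_estimate(test$time[i], test$event[i]))
  h_cal <- horizons[which.min(abs(horizons - 24))]
  pred <- predict_survival(model, test, h_cal)
  if (h_cal <= max(test$time))
    report$calibration <- calibration_table(pred, test$time, test$event, h_cal)
  split_hi <- percentile_risk_split(risk)
  if (sum(split_hi == "high") > 0 && sum(tapply(test$event, split_hi, sum) > 0) == 2) {
    report$risk_split_hr <- cox_pairwise_hr(split_hi, test$time, test$event)
  }
  report$groups_table <- as.data.frame(table(group = groups))
  report
}
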