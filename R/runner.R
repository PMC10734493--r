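#' Build an experiment configuration
#'
#' Collects every knob of a full run in one validated object. `synthetic`
#' holds arguments for [synthetic_spec()] (the usual case for simulation
#' studies); alternatively `cohort_files` names TSV feature tables (one
#' per cohort, dialect of [read_feature_table()]).
#'
#' @param seed root seed; every child stream derives from it.
#' @param repetitions,n_iter,outer_k_max nested CV settings.
#' @param algorithms algorithms to evaluate within-study.
#' @param stages subset of `c("simulate", "diversity", "within", "cross",
#'   "compare")`, executed in that order.
#' @param synthetic list of [synthetic_spec()] arguments (seed is derived
#'   from the root seed automatically).
#' @param cohort_files optional named character vector of TSV paths.
#' @param out_dir output directory for tables and the manifest.
#' @param ... further settings stored verbatim (e.g. `num_trees`,
#'   `n_shuffles`, `importance_reps`, `strategies`, `augmenting_id`).
#' @return an `experiment_config`.
#' @export
experiment_config <- function(seed = 1,
                              repetitions = mc_defaults()$repetitions,
                              n_iter = mc_defaults()$n_iter,
                              outer_k_max = mc_defaults()$outer_k_max,
                              algorithms = "rf",
                              stages = c("simulate", "diversity", "within",
                                         "cross"),
                              synthetic = list(),
                              cohort_files = NULL,
                              out_dir = tempfile("microcross_run_"),
                              ...) {
  stopifnot(repetitions >= 1, n_iter >= 1)
  stages <- match.arg(stages, c("simulate", "diversity", "within", "cross",
                                "compare"), several.ok = TRUE)
  if (is.null(cohort_files) && !("simulate" %in% stages) &&
      length(stages) > 0)
    stop("config needs a cohort source: synthetic simulation or cohort_files",
         call. = FALSE)
  algorithms <- vapply(algorithms, check_algorithm, "")
  structure(c(list(seed = seed, repetitions = repetitions, n_iter = n_iter,
                   outer_k_max = outer_k_max, algorithms = algorithms,
                   stages = stages, synthetic = synthetic,
                   cohort_files = cohort_files, out_dir = out_dir),
              list(...)),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#' @param path YAML file whose keys are [experiment_config()] arguments.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  do.call(experiment_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  seed_stream(0, paste(utils::capture.output(utils::str(
    config[setdiff(names(config), "out_dir")])), collapse = "\n"))
}

#' Run a configured experiment end to end
#'
#' Executes the requested stages in deterministic order — simulate,
#' diversity, within-study nested CV (per cohort x algorithm),
#' leave-one-cohort-out cross-study ensembles, strategy comparison — and
#' writes per-stage TSV/JSON outputs plus a manifest JSON (config hash,
#' package version, child seeds, output paths) under `config$out_dir`.
#' Re-running the same config reproduces every numeric output bitwise.
#'
#' @param config an [experiment_config()].
#' @param cohorts optional pre-built named list of [cohort_dataset()]s
#'   (skips the simulate/load step).
#' @return the manifest, invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
run_experiment <- function(config, cohorts = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("microcross")),
                   config_hash = config_hash(config),
                   seed = config$seed, stages = list(), child_seeds = list(),
                   timestamp = format(Sys.time(), tz = "UTC"))
  out <- function(name) file.path(config$out_dir, name)
  write_tsv <- function(df, name) {
    utils::write.table(df, out(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$stages[[name]] <<- out(name)
    out(name)
  }

  if (is.null(cohorts)) {
    if (!is.null(config$cohort_files)) {
      missing <- config$cohort_files[!file.exists(config$cohort_files)]
      if (length(missing))
        stop("cohort file(s) not found: ", paste(missing, collapse = ", "),
             call. = FALSE)
      cohorts <- lapply(names(config$cohort_files), function(cid) {
        r <- read_feature_table(config$cohort_files[[cid]])
        cohort_dataset(cid, "m1_2", r$labels, list(r$table))
      })
      names(cohorts) <- names(config$cohort_files)
    } else {
      sim_seed <- seed_stream(config$seed, "simulate")
      manifest$child_seeds$simulate <- sim_seed
      spec <- do.call(synthetic_spec, c(config$synthetic, list(seed = sim_seed)))
      sim <- generate_multicohort(spec)
      cohorts <- sim$cohorts
      manifest$truth_marker <- sim$truth$marker_ids
    }
  }
  if (length(cohorts) == 0) stop("no cohorts to analyse", call. = FALSE)

  if ("diversity" %in% config$stages &&
      !is.null(cohorts[[1]]$counts)) {
    div_seed <- seed_stream(config$seed, "diversity")
    manifest$child_seeds$diversity <- div_seed
    div <- compare_alpha_by_delivery(cohorts, seed = div_seed)
    write_tsv(div, "diversity_alpha.tsv")
  }

  evals <- list()
  if (any(c("within", "cross") %in% config$stages)) {
    rows <- list()
    for (cid in names(cohorts)) {
      for (alg in config$algorithms) {
        ev <- run_nested_cv(
          cohorts[[cid]], algorithm = alg,
          n_iter = config$n_iter, repetitions = config$repetitions,
          outer_k_max = config$outer_k_max, seed = config$seed,
          num_trees = if (is.null(config$num_trees))
            mc_defaults()$num_trees else config$num_trees,
          importance = isTRUE(config$importance),
          importance_reps = config$importance_reps,
          keep_models = TRUE)
        evals[[cid]][[alg]] <- ev
        rows[[length(rows) + 1]] <- data.frame(
          cohort_id = cid, algorithm = alg, auc_mean = ev$auc_mean,
          auc_sd = ev$auc_sd, pr_auc_mean = ev$pr_auc_mean,
          pr_auc_sd = ev$pr_auc_sd, stringsAsFactors = FALSE)
      }
    }
    if ("within" %in% config$stages)
      write_tsv(do.call(rbind, rows), "within_study_auc.tsv")
  }

  if ("cross" %in% config$stages) {
    rows <- list()
    for (cid in names(cohorts)) {
      donors <- lapply(setdiff(names(cohorts), cid), function(d)
        select_best_model(evals[[d]]))
      ep <- cross_study_predict(cohorts[[cid]], donors, seed = config$seed,
                                repetitions = config$repetitions,
                                outer_k_max = config$outer_k_max)
      rows[[length(rows) + 1]] <- data.frame(
        cohort_id = cid, n_donors = length(donors),
        auc_mean = ep$auc_mean, auc_sd = ep$auc_sd,
        pr_auc_mean = ep$pr_auc_mean, stringsAsFactors = FALSE)
    }
    write_tsv(do.call(rbind, rows), "cross_study_auc.tsv")
  }

  if ("compare" %in% config$stages) {
    cmp <- compare_strategies(
      cohorts,
      strategies = if (is.null(config$strategies)) c("within", "ensemble")
                   else config$strategies,
      algorithm = config$algorithms[1],
      augmenting_id = config$augmenting_id,
      seed = config$seed, repetitions = config$repetitions,
      n_iter = config$n_iter, outer_k_max = config$outer_k_max)
    write_tsv(cmp, "strategy_comparison.tsv")
  }

  manifest$child_seeds$folds_example <-
    seed_stream(config$seed, "folds", 1)
  manifest_path <- out("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
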