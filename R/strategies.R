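#' Select a cohort's best model from its evaluations
#'
#' Argmax of `auc_mean` over the cohort's `model_evaluation`s; exact ties
#' are broken by algorithm precedence (`rf < extra < lgbm < mlp`), then by
#' route (genera before pathways). The winner's repetition-1 outer-fold
#' refits become the cohort's contribution to cross-study ensembles.
#'
#' @param evaluations list of `model_evaluation`s for one cohort (each with
#'   `keep_models = TRUE`).
#' @return a `best_model_spec`: cohort_id, algorithm, route, auc_mean and
#'   the list of fitted fold models.
#' @export
select_best_model <- function(evaluations) {
  if (length(evaluations) == 0) stop("no evaluations supplied", call. = FALSE)
  stopifnot(all(vapply(evaluations, inherits, TRUE, "model_evaluation")))
  cid <- unique(vapply(evaluations, `[[`, "", "cohort_id"))
  if (length(cid) != 1)
    stop("evaluations must all belong to one cohort", call. = FALSE)
  alg_rank <- match(vapply(evaluations, `[[`, "", "algorithm"), algorithm_ids())
  route1 <- vapply(evaluations, function(e) e$route[1], "")
  route_rank <- ifelse(grepl("genera", route1), 1L, 2L)
  ord <- order(-vapply(evaluations, `[[`, 0, "auc_mean"), alg_rank, route_rank)
  best <- evaluations[[ord[1]]]
  if (length(best$models) == 0)
    stop("winning evaluation kept no fitted models (keep_models = FALSE?)",
         call. = FALSE)
  structure(list(cohort_id = best$cohort_id, algorithm = best$algorithm,
                 route = best$route[1], auc_mean = best$auc_mean,
                 models = best$models),
            class = "best_model_spec")
}

#' @export
print.best_model_spec <- function(x, ...) {
  cat(sprintf("<best_model_spec> %s: %s on %s (AUC %.3f, %d fold models)\n",
              x$cohort_id, x$algorithm, x$route, x$auc_mean,
              length(x$models)))
  invisible(x)
}

# mean positive-class probability of one donor's fold models on a matrix
donor_probs <- function(donor, x) {
  rowMeans(vapply(donor$models, function(m) predict_proba(m, x),
                  numeric(nrow(x))))
}

# ensemble scoring function over donors: unweighted mean of donor means
ensemble_scorer <- function(donors) {
  function(x) rowMeans(vapply(donors, function(d) donor_probs(d, x),
                              numeric(nrow(x))))
}

#' Cross-study ensemble prediction on a target cohort
#'
#' Each donor cohort contributes the mean positive-class probability of its
#' fold models; the ensemble probability is the unweighted mean over
#' donors. Predictions are organized by the target's own outer
#' cross-validation folds — [plan_folds()] at the same seed produces splits
#' identical to the target's within-study run, so within- and cross-study
#' AUCs are computed on the same validation samples. Target labels are
#' used only to compute AUC, never for scoring.
#'
#' @param target a [cohort_dataset()].
#' @param donors list of `best_model_spec`s, none from the target cohort.
#' @param route target route whose table feeds the models (key or tag;
#'   `NULL` = only route).
#' @param seed root seed (use the within-study seed for fold alignment).
#' @param repetitions repetitions (fold plans re-drawn per repetition).
#' @param outer_k_max maximum fold count, matching the within-study run.
#' @return an `ensemble_prediction`: per-repetition pooled predictions,
#'   `auc_rep`, `auc_mean`, `auc_sd`, `pr_auc_mean`, donor ids.
#' @export
cross_study_predict <- function(target, donors, route = NULL, seed = 1,
                                repetitions = mc_defaults()$repetitions,
                                outer_k_max = mc_defaults()$outer_k_max) {
  stopifnot(inherits(target, "cohort_dataset"), length(donors) >= 1,
            all(vapply(donors, inherits, TRUE, "best_model_spec")))
  donor_ids <- vapply(donors, `[[`, "", "cohort_id")
  if (target$cohort_id %in% donor_ids)
    stop("donors must exclude the target cohort", call. = FALSE)
  tab <- get_route(target, route)
  spaces <- unique(vapply(donors, function(d)
    sub("^.*:", "", d$route), ""))
  if (!all(spaces == tab$route$feature_space))
    stop("donor feature space (", paste(spaces, collapse = ","),
         ") does not match target route '", route_key(tab$route),
         "'; align routes first", call. = FALSE)
  x <- tab$values
  y <- target$labels
  ids <- tab$sample_ids
  # donor probabilities are fixed functions of the features: compute once
  per_donor <- vapply(donors, function(d) donor_probs(d, x),
                      numeric(nrow(x)))
  ens <- rowMeans(per_donor)
  preds <- list()
  auc_rep <- numeric(repetitions); pr_rep <- numeric(repetitions)
  plans <- vector("list", repetitions)
  for (rep_i in seq_len(repetitions)) {
    plan <- plan_folds(y, outer_k_max, seed, rep_i)
    plans[[rep_i]] <- plan
    preds[[rep_i]] <- data.frame(
      repetition = rep_i, fold = plan$outer, sample_id = ids,
      label = as.character(y), prob = ens, stringsAsFactors = FALSE)
    auc_rep[rep_i] <- roc_auc(y, ens)
    pr_rep[rep_i] <- pr_auc(y, ens)
  }
  structure(list(cohort_id = target$cohort_id, donor_ids = donor_ids,
                 repetitions = repetitions,
                 probabilities = stats::setNames(ens, ids),
                 donor_probabilities = per_donor,
                 predictions = do.call(rbind, preds),
                 auc_rep = auc_rep,
                 auc_mean = mean(auc_rep), auc_sd = stats::sd(auc_rep),
                 pr_auc_mean = mean(pr_rep), pr_auc_sd = stats::sd(pr_rep),
                 fold_plans = plans, seed = seed),
            class = "ensemble_prediction")
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat(sprintf("<ensemble_prediction> target %s from donors {%s}: AUC %.3f (SD %.3f)\n",
              x$cohort_id, paste(x$donor_ids, collapse = ", "),
              x$auc_mean, x$auc_sd))
  invisible(x)
}

#' Permutation importance of a cross-study ensemble on its target
#'
#' The donor ensemble is treated as a single scoring function (see
#' [predict_proba()]); features of the target table are permuted across
#' the pooled target samples, `repetitions` times with fresh shuffles, and
#' the per-repetition reports are averaged.
#'
#' @inheritParams cross_study_predict
#' @param n_shuffles shuffles per feature per repetition.
#' @param repetitions importance repetitions (default 1; shuffle noise is
#'   already averaged over `n_shuffles`).
#' @return an aggregated `importance_report`.
#' @export
ensemble_importance <- function(target, donors, route = NULL,
                                n_shuffles = mc_defaults()$n_shuffles,
                                seed = 1, repetitions = 1) {
  stopifnot(length(donors) >= 1,
            all(vapply(donors, inherits, TRUE, "best_model_spec")))
  if (target$cohort_id %in% vapply(donors, `[[`, "", "cohort_id"))
    stop("donors must exclude the target cohort", call. = FALSE)
  tab <- get_route(target, route)
  scorer <- ensemble_scorer(donors)
  reports <- lapply(seq_len(repetitions), function(rep_i) {
    permutation_importance(scorer, tab$values, target$labels,
                           n_shuffles = n_shuffles,
                           seed = seed_stream(seed, "ens_importance",
                                              target$cohort_id, rep_i))
  })
  aggregate_importance(reports)
}

#' Draw augmenting control samples for one training fold
#'
#' Control augmenting raises the number of control-class (vaginal) samples
#' in a training fold `factor`-fold: with `n` controls in the fold,
#' `(factor - 1) * n` controls are drawn without replacement from the
#' augmenting cohort (all of them if it has fewer). The augmenting cohort
#' must differ from the evaluated cohort, and validation folds are never
#' touched; a cohort that augments others is ineligible for model building
#' and cross-study validation in its stratum (see [eligible_cohorts()]).
#'
#' @param train_ids,train_labels the training fold's sample ids and labels.
#' @param augmenting the augmenting [cohort_dataset()].
#' @param route route of the augmenting table to draw features from
#'   (key or tag; `NULL` = only route).
#' @param control_class class being augmented (default `"vaginal"`).
#' @param factor target multiplier (default 5); `factor = 1` adds nothing.
#' @param seed draw seed.
#' @param target_cohort_id optional evaluated-cohort id for the leakage
#'   guard (augmenting cohort == evaluated cohort is an error).
#' @return list with `x` (augmenting feature matrix rows), `labels`,
#'   `ids` (prefixed with the augmenting cohort id) and `n_requested`.
#' @export
augment_training <- function(train_ids, train_labels, augmenting,
                             route = NULL, control_class = "vaginal",
                             factor = mc_defaults()$augment_factor, seed = 1,
                             target_cohort_id = NULL) {
  stopifnot(inherits(augmenting, "cohort_dataset"), factor >= 1)
  if (!is.null(target_cohort_id) &&
      identical(target_cohort_id, augmenting$cohort_id))
    stop("augmenting cohort equals the evaluated cohort: information would ",
         "leak between validation folds", call. = FALSE)
  labels <- as_delivery_mode(train_labels)
  n_controls <- sum(labels == control_class)
  n_requested <- (factor - 1) * n_controls
  tab <- get_route(augmenting, route)
  pool <- which(as.character(augmenting$labels) == control_class)
  if (length(pool) == 0)
    stop("augmenting cohort has no ", control_class, " samples", call. = FALSE)
  n_take <- min(n_requested, length(pool))
  take <- if (n_take == 0) integer(0) else {
    with_stream(seed, "augment_draw", code = pool[sample.int(length(pool),
                                                             n_take)])
  }
  ids <- if (n_take == 0) character(0) else
    paste0(augmenting$cohort_id, ":", tab$sample_ids[take])
  list(x = tab$values[take, , drop = FALSE],
       labels = factor(rep(control_class, n_take), levels = .mc_levels),
       ids = ids, n_requested = n_requested)
}

#' Which cohorts may be evaluated under a strategy
#'
#' Under control augmenting, the augmenting cohort is excluded from model
#' building and from cross-study validation in its stratum, because its
#' samples sit in every other cohort's training folds.
#'
#' @param cohorts named list of [cohort_dataset()]s.
#' @param strategy one of `"genera"`, `"pathways"`, `"augment"`,
#'   `"pipeline_search"`.
#' @param augmenting_id cohort id used for augmenting (required when
#'   `strategy = "augment"`).
#' @return character vector of evaluable cohort ids.
#' @export
eligible_cohorts <- function(cohorts, strategy = "genera",
                             augmenting_id = NULL) {
  ids <- vapply(cohorts, `[[`, "", "cohort_id")
  if (strategy == "augment") {
    if (is.null(augmenting_id))
      stop("augment strategy needs an augmenting cohort id", call. = FALSE)
    ids <- setdiff(ids, augmenting_id)
  }
  unname(ids)
}

#' Nested cross-validation with the preprocessing route as a hyperparameter
#'
#' Pipeline search: every candidate configuration additionally carries a
#' route drawn uniformly from the available routes (from a dedicated seed
#' stream, so with a single route the run is bit-identical to
#' [run_nested_cv()]). Inner scoring and the final refit use the
#' candidate's route; the chosen route of every outer fold is recorded in
#' the evaluation's `chosen` table. Fold plans depend only on labels and
#' seed, so they are identical to the plain run's.
#'
#' @inheritParams run_nested_cv
#' @param routes route keys to search over (default: all routes of the
#'   dataset). All routes must cover identical samples.
#' @return a `model_evaluation` (with `pipeline_search = TRUE` when more
#'   than one route is searched).
#' @export
pipeline_search <- function(dataset, routes = NULL, algorithm = "rf",
                            n_iter = mc_defaults()$n_iter,
                            repetitions = mc_defaults()$repetitions,
                            outer_k_max = mc_defaults()$outer_k_max,
                            seed = 1, space = NULL,
                            num_trees = mc_defaults()$num_trees,
                            importance = FALSE, importance_reps = NULL,
                            n_shuffles = mc_defaults()$n_shuffles,
                            keep_models = TRUE) {
  if (is.null(routes)) routes <- routes_of(dataset)
  run_nested_cv_core(dataset, routes = routes, algorithm = algorithm,
                     n_iter = n_iter, repetitions = repetitions,
                     outer_k_max = outer_k_max, seed = seed, space = space,
                     num_trees = num_trees, importance = importance,
                     importance_reps = importance_reps,
                     n_shuffles = n_shuffles, augment = NULL,
                     keep_models = keep_models)
}

#' Compare model-building strategies across cohorts
#'
#' Runs, per eligible cohort: within-study nested CV on the primary route,
#' the leave-one-cohort-out ensemble on that route, and optionally the
#' augmented and pipeline-search variants, returning a tidy strategy x
#' cohort AUC table.
#'
#' @param cohorts named list of [cohort_dataset()]s (aligned features).
#' @param strategies subset of
#'   `c("within", "ensemble", "augment", "pipeline_search")`.
#' @param algorithm algorithm for within-study runs.
#' @param augmenting_id augmenting cohort id (for `"augment"`).
#' @param route primary route key (`NULL` = first route).
#' @param ... passed to [run_nested_cv()] / [pipeline_search()]
#'   (`n_iter`, `repetitions`, `outer_k_max`, `seed`, ...).
#' @return data frame with columns `strategy, cohort_id, auc_mean, auc_sd`.
#' @export
compare_strategies <- function(cohorts,
                               strategies = c("within", "ensemble"),
                               algorithm = "rf", augmenting_id = NULL,
                               route = NULL, ...) {
  stopifnot(length(cohorts) >= 2)
  if (is.null(route)) route <- routes_of(cohorts[[1]])[1]
  dots <- list(...)
  seed <- if (is.null(dots$seed)) 1 else dots$seed
  okm <- if (is.null(dots$outer_k_max)) mc_defaults()$outer_k_max else
    dots$outer_k_max
  reps <- if (is.null(dots$repetitions)) mc_defaults()$repetitions else
    dots$repetitions
  rows <- list()
  evals <- list()
  run_within <- function(ds, aug = NULL) {
    do.call(run_nested_cv, c(list(dataset = ds, route = route,
                                  algorithm = algorithm, augment = aug,
                                  importance = FALSE), dots))
  }
  if (any(c("within", "ensemble") %in% strategies)) {
    for (cid in names(cohorts)) evals[[cid]] <- run_within(cohorts[[cid]])
  }
  if ("within" %in% strategies) {
    for (cid in names(cohorts)) {
      rows[[length(rows) + 1]] <- data.frame(
        strategy = "within", cohort_id = cid,
        auc_mean = evals[[cid]]$auc_mean, auc_sd = evals[[cid]]$auc_sd,
        stringsAsFactors = FALSE)
    }
  }
  if ("ensemble" %in% strategies) {
    for (cid in names(cohorts)) {
      donors <- lapply(evals[setdiff(names(cohorts), cid)],
                       function(e) select_best_model(list(e)))
      ep <- cross_study_predict(cohorts[[cid]], donors, route = route,
                                seed = seed, repetitions = reps,
                                outer_k_max = okm)
      rows[[length(rows) + 1]] <- data.frame(
        strategy = "ensemble", cohort_id = cid,
        auc_mean = ep$auc_mean, auc_sd = ep$auc_sd, stringsAsFactors = FALSE)
    }
  }
  if ("augment" %in% strategies) {
    elig <- eligible_cohorts(cohorts, "augment", augmenting_id)
    for (cid in elig) {
      ev <- run_within(cohorts[[cid]],
                       aug = list(dataset = cohorts[[augmenting_id]]))
      rows[[length(rows) + 1]] <- data.frame(
        strategy = "augment", cohort_id = cid,
        auc_mean = ev$auc_mean, auc_sd = ev$auc_sd, stringsAsFactors = FALSE)
    }
  }
  if ("pipeline_search" %in% strategies) {
    for (cid in names(cohorts)) {
      ev <- do.call(pipeline_search, c(list(dataset = cohorts[[cid]],
                                            algorithm = algorithm), dots))
      rows[[length(rows) + 1]] <- data.frame(
        strategy = "pipeline_search", cohort_id = cid,
        auc_mean = ev$auc_mean, auc_sd = ev$auc_sd, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
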