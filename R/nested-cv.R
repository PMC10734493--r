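#' Permutation feature importance of a scorer on test data
#'
#' For each feature, the importance is `AUC(original) - mean over
#' n_shuffles of AUC(with that feature's column permuted across the test
#' samples)`; all other columns are untouched. A feature the scorer
#' ignores, or one constant across the test samples, gets importance 0.
#' Deterministic given `seed`. Predictions for all (feature, shuffle)
#' pairs are batched into a single `predict_proba()` call per block,
#' which matters for forest backends with per-call overhead.
#'
#' @param model a `trained_model` or scoring function (see
#'   [predict_proba()]).
#' @param x test matrix (samples x features, named columns).
#' @param labels test labels, both classes present.
#' @param n_shuffles permutations per feature (default 5).
#' @param seed integer seed.
#' @param batch_rows cap on rows per batched predict call.
#' @return an `importance_report` data frame: `feature`, `mean_reduction`,
#'   `sd_reduction` (SD across the shuffles), `rank` (1 = most important,
#'   ties broken by feature id).
#' @export
permutation_importance <- function(model, x, labels,
                                   n_shuffles = mc_defaults()$n_shuffles,
                                   seed = 1, batch_rows = 200000) {
  stopifnot(is.matrix(x), nrow(x) >= 1)
  if (nrow(x) == 0) stop("empty test set", call. = FALSE)
  y <- as_binary01(labels)
  if (length(unique(y)) < 2)
    stop("test labels must contain both classes", call. = FALSE)
  base <- roc_auc(y, predict_proba(model, x))
  n <- nrow(x); p <- ncol(x)
  perms <- with_stream(seed, "perm_importance", code = {
    lapply(seq_len(n_shuffles * p), function(i) sample.int(n))
  })
  # block the (feature, shuffle) grid so each block is one predict call
  jobs <- expand.grid(shuffle = seq_len(n_shuffles), feature = seq_len(p))
  per_block <- max(1L, floor(batch_rows / n))
  auc_drop <- matrix(NA_real_, n_shuffles, p)
  i <- 1L
  while (i <= nrow(jobs)) {
    idx <- i:min(i + per_block - 1L, nrow(jobs))
    big <- x[rep(seq_len(n), length(idx)), , drop = FALSE]
    for (k in seq_along(idx)) {
      j <- jobs$feature[idx[k]]; s <- jobs$shuffle[idx[k]]
      rows <- (k - 1L) * n + seq_len(n)
      big[rows, j] <- x[perms[[(j - 1L) * n_shuffles + s]], j]
    }
    probs <- predict_proba(model, big)
    for (k in seq_along(idx)) {
      rows <- (k - 1L) * n + seq_len(n)
      auc_drop[jobs$shuffle[idx[k]], jobs$feature[idx[k]]] <-
        base - roc_auc(y, probs[rows])
    }
    i <- i + per_block
  }
  new_importance_report(colnames(x),
                        mean_reduction = colMeans(auc_drop),
                        sd_reduction = apply(auc_drop, 2, stats::sd))
}

new_importance_report <- function(features, mean_reduction, sd_reduction) {
  ord <- order(-mean_reduction, features)
  rank <- integer(length(features)); rank[ord] <- seq_along(features)
  structure(data.frame(feature = features, mean_reduction = mean_reduction,
                       sd_reduction = sd_reduction, rank = rank,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("importance_report", "data.frame"))
}

#' Average importance reports across repetitions/folds
#'
#' Per-feature mean and SD of the per-report mean reductions; rank by mean
#' descending, ties broken by feature id.
#'
#' @param reports list of `importance_report`s over the same feature set.
#' @return an aggregated `importance_report`.
#' @export
aggregate_importance <- function(reports) {
  stopifnot(length(reports) >= 1)
  feats <- reports[[1]]$feature
  vals <- vapply(reports, function(r) {
    if (!identical(sort(r$feature), sort(feats)))
      stop("importance reports cover different feature sets", call. = FALSE)
    r$mean_reduction[match(feats, r$feature)]
  }, numeric(length(feats)))
  vals <- matrix(vals, nrow = length(feats))
  new_importance_report(feats,
                        mean_reduction = rowMeans(vals),
                        sd_reduction = apply(vals, 1, stats::sd))
}

# Score one candidate by mean inner-fold ROC AUC
score_candidate_inner <- function(config, x, y, inner, seed, num_trees) {
  aucs <- vapply(seq_len(max(inner$fold)), function(g) {
    tr <- inner$idx[inner$fold != g]
    va <- inner$idx[inner$fold == g]
    m <- fit_candidate(config, x[tr, , drop = FALSE], y[tr],
                       seed = seed, num_trees = num_trees)
    roc_auc(y[va], predict_proba(m, x[va, , drop = FALSE]))
  }, 0)
  mean(aucs)
}

#' Seeded nested cross-validation of one algorithm on one cohort
#'
#' For each repetition, plans stratified folds with [plan_folds()] (a
#' function of labels and seed only, so every algorithm and strategy sees
#' identical splits). Within each outer fold, `n_iter` candidate
#' configurations are drawn, each scored by its mean inner-fold ROC AUC;
#' the best candidate (ties: first in sampled order) is refit on the full
#' outer-training set and predicts the validation fold. The
#' per-repetition ROC/PR AUC is computed on that repetition's pooled
#' outer-fold predictions, and means/SDs are taken over repetitions.
#' Permutation importance is measured per outer fold on the validation
#' samples and averaged.
#'
#' @param dataset a [cohort_dataset()].
#' @param route route to use (key or [route_tag()]; `NULL` = only route).
#' @param algorithm one of [algorithm_ids()].
#' @param n_iter randomized-search iterations per outer fold (default 40).
#' @param repetitions nested CV repetitions (default 40).
#' @param outer_k_max maximum fold count (default 10).
#' @param seed root seed.
#' @param space hyperparameter space (default [default_space()] of the
#'   algorithm).
#' @param num_trees forest size for rf/extra.
#' @param importance compute permutation importance (default TRUE).
#' @param importance_reps repetitions on which importance is measured
#'   (default: all of `1..repetitions`). Importance costs one batched
#'   predict per fold; restricting it to the first repetition(s) is the
#'   standard way to scale a run down.
#' @param n_shuffles shuffles per feature and fold for importance.
#' @param augment optional control augmenting: a list
#'   `list(dataset = <cohort_dataset>, factor = 5)` naming the augmenting
#'   cohort; see [augment_training()]. Augmented controls join only
#'   training folds (inner and outer refit), never validation folds.
#' @param keep_models keep the repetition-1 outer-fold refits (needed to
#'   act as a donor in [cross_study_predict()]; default TRUE).
#' @return a `model_evaluation`: cohort/algorithm/route ids, per-repetition
#'   AUCs (`auc_rep`, `pr_auc_rep`), `auc_mean/auc_sd/pr_auc_mean/pr_auc_sd`,
#'   a `predictions` data frame (repetition, fold, sample_id, label, prob),
#'   `chosen` (per repetition x fold: the selected candidate, incl. route),
#'   `importance` (aggregated report or NULL), `models` (repetition-1
#'   refits) and `fold_plans`.
#' @export
run_nested_cv <- function(dataset, route = NULL, algorithm = "rf",
                          n_iter = mc_defaults()$n_iter,
                          repetitions = mc_defaults()$repetitions,
                          outer_k_max = mc_defaults()$outer_k_max,
                          seed = 1, space = NULL,
                          num_trees = mc_defaults()$num_trees,
                          importance = TRUE, importance_reps = NULL,
                          n_shuffles = mc_defaults()$n_shuffles,
                          augment = NULL, keep_models = TRUE) {
  algorithm <- check_algorithm(algorithm)
  routes <- if (is.null(route)) routes_of(dataset)[1] else {
    if (inherits(route, "route_tag")) route_key(route) else route
  }
  run_nested_cv_core(dataset, routes = routes, algorithm = algorithm,
                     n_iter = n_iter, repetitions = repetitions,
                     outer_k_max = outer_k_max, seed = seed, space = space,
                     num_trees = num_trees, importance = importance,
                     importance_reps = importance_reps,
                     n_shuffles = n_shuffles, augment = augment,
                     keep_models = keep_models)
}

# Shared engine for run_nested_cv (single route) and pipeline_search
# (several routes: the route is drawn per candidate from a separate seed
# stream, so a single-route call is bit-identical to run_nested_cv).
run_nested_cv_core <- function(dataset, routes, algorithm, n_iter,
                               repetitions, outer_k_max, seed, space,
                               num_trees, importance, importance_reps,
                               n_shuffles, augment, keep_models) {
  stopifnot(inherits(dataset, "cohort_dataset"), repetitions >= 1, n_iter >= 1)
  for (r in routes) get_route(dataset, r)  # validate presence
  if (length(routes) > 1) {
    ids0 <- dataset$tables[[routes[1]]]$sample_ids
    for (r in routes[-1]) {
      if (!identical(dataset$tables[[r]]$sample_ids, ids0))
        stop("routes cover different samples", call. = FALSE)
    }
  }
  if (is.null(space)) space <- default_space(algorithm)
  y <- dataset$labels
  ids <- dataset$tables[[1]]$sample_ids
  xs <- lapply(dataset$tables[routes], `[[`, "values")
  if (is.null(importance_reps)) importance_reps <- seq_len(repetitions)
  if (!is.null(augment)) {
    stopifnot(is.list(augment), inherits(augment$dataset, "cohort_dataset"))
    if (identical(augment$dataset$cohort_id, dataset$cohort_id))
      stop("augmenting cohort must differ from the evaluated cohort",
           call. = FALSE)
    if (is.null(augment$factor)) augment$factor <- mc_defaults()$augment_factor
  }
  cid <- dataset$cohort_id
  preds <- list(); chosen <- list(); reports <- list()
  augmented_ids <- character(0)
  auc_rep <- numeric(repetitions); pr_rep <- numeric(repetitions)
  models <- list(); plans <- vector("list", repetitions)

  for (rep_i in seq_len(repetitions)) {
    plan <- plan_folds(y, outer_k_max, seed, rep_i)
    plans[[rep_i]] <- plan
    for (f in seq_len(plan$outer_k)) {
      tr <- plan$inner[[f]]$idx
      va <- which(plan$outer == f)
      cands <- sample_candidates(space, n_iter,
                                 seed = seed_stream(seed, "cand", cid, rep_i, f))
      if (length(routes) > 1) {
        picks <- with_stream(seed, "route", cid, rep_i, f, code = {
          sample(routes, length(cands), replace = TRUE)
        })
        for (ci in seq_along(cands)) cands[[ci]]$route <- picks[[ci]]
      } else {
        for (ci in seq_along(cands)) cands[[ci]]$route <- routes[1]
      }
      fit_seed <- seed_stream(seed, "fit", cid, rep_i, f)
      # optional control augmenting for this training fold
      aug_data <- NULL
      if (!is.null(augment)) {
        aug_data <- augment_training(
          train_ids = ids[tr], train_labels = y[tr],
          augmenting = augment$dataset,
          route = routes[1], factor = augment$factor,
          seed = seed_stream(seed, "augment", cid, rep_i, f),
          target_cohort_id = cid)
        augmented_ids <- union(augmented_ids, aug_data$ids)
      }
      scores <- vapply(cands, function(cfg) {
        x <- xs[[cfg$route]]
        if (is.null(aug_data)) {
          score_candidate_inner(cfg, x, y, plan$inner[[f]], fit_seed, num_trees)
        } else {
          score_candidate_inner_augmented(cfg, x, y, plan$inner[[f]],
                                          aug_data, fit_seed, num_trees)
        }
      }, 0)
      best <- cands[[which.max(scores)]]  # ties: first in sampled order
      xb <- xs[[best$route]]
      if (is.null(aug_data)) {
        final <- fit_candidate(best, xb[tr, , drop = FALSE], y[tr],
                               seed = fit_seed, num_trees = num_trees)
      } else {
        xa <- rbind(xb[tr, , drop = FALSE],
                    reindex_matrix(aug_data$x, colnames(xb)))
        ya <- factor(c(as.character(y[tr]), as.character(aug_data$labels)),
                     levels = levels(y))
        final <- fit_candidate(best, xa, ya, seed = fit_seed,
                               num_trees = num_trees)
      }
      prob <- predict_proba(final, xb[va, , drop = FALSE])
      preds[[length(preds) + 1]] <- data.frame(
        repetition = rep_i, fold = f, sample_id = ids[va],
        label = as.character(y[va]), prob = prob, stringsAsFactors = FALSE)
      chosen[[length(chosen) + 1]] <- data.frame(
        repetition = rep_i, fold = f, algorithm = algorithm,
        route = best$route, config = format(best),
        inner_auc = max(scores), stringsAsFactors = FALSE)
      if (importance && rep_i %in% importance_reps) {
        reports[[length(reports) + 1]] <- permutation_importance(
          final, xb[va, , drop = FALSE], y[va], n_shuffles = n_shuffles,
          seed = seed_stream(seed, "importance", cid, rep_i, f))
      }
      if (keep_models && rep_i == 1) {
        models[[length(models) + 1]] <- final
      }
    }
    rep_preds <- do.call(rbind, preds[vapply(preds, function(d)
      d$repetition[1], 0) == rep_i])
    auc_rep[rep_i] <- roc_auc(rep_preds$label, rep_preds$prob)
    pr_rep[rep_i] <- pr_auc(rep_preds$label, rep_preds$prob)
  }

  structure(list(
    cohort_id = cid, algorithm = algorithm,
    route = if (length(routes) == 1) routes else routes,
    pipeline_search = length(routes) > 1,
    repetitions = repetitions,
    auc_rep = auc_rep, pr_auc_rep = pr_rep,
    auc_mean = mean(auc_rep), auc_sd = stats::sd(auc_rep),
    pr_auc_mean = mean(pr_rep), pr_auc_sd = stats::sd(pr_rep),
    predictions = do.call(rbind, preds),
    chosen = do.call(rbind, chosen),
    importance = if (length(reports)) aggregate_importance(reports) else NULL,
    models = models, fold_plans = plans,
    augmented_ids = augmented_ids,
    seed = seed, outer_k_max = outer_k_max),
    class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("<model_evaluation> %s / %s%s: AUC %.3f (SD %.3f), PR AUC %.3f (SD %.3f) over %d repetitions\n",
              x$cohort_id, x$algorithm,
              if (isTRUE(x$pipeline_search)) " [pipeline search]" else "",
              x$auc_mean, x$auc_sd, x$pr_auc_mean, x$pr_auc_sd,
              x$repetitions))
  invisible(x)
}

# inner scoring with augmented controls added to the inner-training part
score_candidate_inner_augmented <- function(config, x, y, inner, aug_data,
                                            seed, num_trees) {
  aug_x <- reindex_matrix(aug_data$x, colnames(x))
  aucs <- vapply(seq_len(max(inner$fold)), function(g) {
    tr <- inner$idx[inner$fold != g]
    va <- inner$idx[inner$fold == g]
    xa <- rbind(x[tr, , drop = FALSE], aug_x)
    ya <- factor(c(as.character(y[tr]), as.character(aug_data$labels)),
                 levels = levels(y))
    m <- fit_candidate(config, xa, ya, seed = seed, num_trees = num_trees)
    roc_auc(y[va], predict_proba(m, x[va, , drop = FALSE]))
  }, 0)
  mean(aucs)
}
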