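mk_eval <- function(cohort = "A", algorithm = "rf", auc = 0.8,
                    route = "synthetic:genera") {
  structure(list(cohort_id = cohort, algorithm = algorithm, route = route,
                 auc_mean = auc, models = list(function(x) rep(0.5, nrow(x)))),
            class = "model_evaluation")
}

test_that("best-model selection maximizes AUC with precedence tie-breaks", {
  pick <- select_best_model(list(mk_eval(algorithm = "rf", auc = 0.82),
                                 mk_eval(algorithm = "lgbm", auc = 0.75)))
  expect_equal(pick$algorithm, "rf")
  tie <- select_best_model(list(mk_eval(algorithm = "mlp", auc = 0.8),
                                mk_eval(algorithm = "rf", auc = 0.8)))
  expect_equal(tie$algorithm, "rf")  # precedence rf < extra < lgbm < mlp
  route_tie <- select_best_model(list(
    mk_eval(auc = 0.8, route = "synthetic:pathways"),
    mk_eval(auc = 0.8, route = "synthetic:genera")))
  expect_equal(route_tie$route, "synthetic:genera")
  single <- select_best_model(list(mk_eval(auc = 0.6)))
  expect_equal(single$auc_mean, 0.6)
  expect_error(select_best_model(list()), "no evaluations")
  expect_error(select_best_model(list(mk_eval(cohort = "A"),
                                      mk_eval(cohort = "B"))), "one cohort")
})

test_that("ensemble probabilities are the exact mean of donor probabilities", {
  world <- small_world(n_cohorts = 1, n = 40, n_taxa = 6, seed = 19)
  ds <- world$cohorts[[1]]
  n <- length(ds$labels)
  # single donor: ensemble equals that donor's (mean-model) output
  d1 <- fn_donor("D1", list(function(x) x[, 1] / max(x[, 1])))
  e1 <- cross_study_predict(ds, list(d1), seed = 4, repetitions = 2,
                            outer_k_max = 4)
  expect_equal(unname(e1$probabilities),
               unname(ds$tables[[1]]$values[, 1] /
                        max(ds$tables[[1]]$values[, 1])))
  # two donors emitting p and 1-p cancel to 0.5 everywhere, AUC 0.5
  p_fun <- function(x) (seq_len(nrow(x)) - 1) / nrow(x)
  e2 <- cross_study_predict(ds, list(fn_donor("D1", list(p_fun)),
                                     fn_donor("D2", list(function(x)
                                       1 - p_fun(x)))),
                            seed = 4, repetitions = 1, outer_k_max = 4)
  expect_true(all(abs(e2$probabilities - 0.5) < 1e-12))
  expect_equal(e2$auc_mean, 0.5)
  # k donors: ensemble is the arithmetic mean to 1e-12
  fns <- lapply(1:4, function(k) function(x) rep(k / 10, nrow(x)))
  donors <- lapply(1:4, function(k) fn_donor(paste0("D", k), fns[k]))
  ek <- cross_study_predict(ds, donors, seed = 4, repetitions = 1,
                            outer_k_max = 4)
  expect_true(all(abs(ek$probabilities - mean(1:4 / 10)) < 1e-12))
  # per repetition, every target sample is predicted exactly once
  per_rep <- split(e1$predictions$sample_id, e1$predictions$repetition)
  for (ids in per_rep) {
    expect_setequal(ids, ds$tables[[1]]$sample_ids)
    expect_equal(anyDuplicated(ids), 0)
  }
  # donor set must not contain the target
  expect_error(cross_study_predict(ds, list(fn_donor(ds$cohort_id,
                                                     list(p_fun)))),
               "exclude the target")
})

test_that("cross-study folds coincide with the within-study plans at one seed", {
  world <- small_world(n_cohorts = 2, n = 60, n_taxa = 10, seed = 29)
  a <- world$cohorts[[1]]; b <- world$cohorts[[2]]
  ev_b <- run_nested_cv(b, algorithm = "rf", n_iter = 2, repetitions = 2,
                        outer_k_max = 4, seed = 6, importance = FALSE)
  ev_a <- run_nested_cv(a, algorithm = "rf", n_iter = 2, repetitions = 2,
                        outer_k_max = 4, seed = 6, importance = FALSE)
  cp <- cross_study_predict(a, list(select_best_model(list(ev_b))),
                            seed = 6, repetitions = 2, outer_k_max = 4)
  for (r in 1:2) {
    expect_identical(cp$fold_plans[[r]]$outer, ev_a$fold_plans[[r]]$outer)
  }
})

test_that("transfer fails when the class effect is not shared across cohorts", {
  # batch structure only: nothing transferable
  sim <- generate_multicohort(synthetic_spec(
    n_cohorts = 2, samples_per_cohort = 300, n_taxa = 30, effect_size = 0,
    batch_sd = 0.8, seed = 404))
  a <- sim$cohorts[[1]]; b <- sim$cohorts[[2]]
  ev_b <- run_nested_cv(b, algorithm = "rf", n_iter = 2, repetitions = 1,
                        outer_k_max = 3, seed = 8, importance = FALSE)
  cp <- cross_study_predict(a, list(select_best_model(list(ev_b))),
                            seed = 8, repetitions = 1, outer_k_max = 3)
  expect_gte(cp$auc_mean, 0.35); expect_lte(cp$auc_mean, 0.65)
})

test_that("ensemble importance recovers the marker and zeroes absent features", {
  world <- small_world(n_cohorts = 2, n = 100, n_taxa = 12, effect = 2,
                       seed = 37)
  a <- world$cohorts[[1]]; b <- world$cohorts[[2]]
  ev_b <- run_nested_cv(b, algorithm = "rf", n_iter = 3, repetitions = 1,
                        outer_k_max = 4, seed = 10, importance = FALSE)
  donors <- list(select_best_model(list(ev_b)))
  imp <- ensemble_importance(a, donors, n_shuffles = 3, seed = 2)
  expect_equal(imp$feature[imp$rank == 1], world$truth$marker_ids)
  # a feature zeroed in the target (absent taxon after union alignment)
  a0 <- a
  a0$tables[[1]]$values[, "g007"] <- 0
  a0$tables[[1]]$values <- a0$tables[[1]]$values /
    rowSums(a0$tables[[1]]$values)
  imp0 <- ensemble_importance(a0, donors, n_shuffles = 3, seed = 2)
  expect_equal(imp0$mean_reduction[imp0$feature == "g007"], 0)
})

test_that("control augmenting draws the documented counts and guards leakage", {
  world <- small_world(n_cohorts = 3, n = 60, n_taxa = 8, seed = 41)
  donor_big <- world$cohorts[[2]]   # 42 vaginal controls
  train_ids <- paste0("t", 1:14)
  train_labels <- rep(c("vaginal", "caesarean"), c(10, 4))
  aug <- augment_training(train_ids, train_labels, donor_big, factor = 5,
                          seed = 1)
  expect_equal(aug$n_requested, 40)
  expect_equal(length(aug$ids), 40)  # donor has enough: 10 -> 50 controls
  expect_true(all(aug$labels == "vaginal"))
  expect_equal(anyDuplicated(aug$ids), 0)
  # exhaustion: donor with only 25 controls gives 10 + 25 = 35
  small_donor <- local({
    m <- matrix(runif(35 * 3) + 0.1, 35, 3,
                dimnames = list(paste0("d", 1:35), c("g1", "g2", "g3")))
    cohort_dataset("DSMALL", "m1_2",
                   rep(c("vaginal", "caesarean"), c(25, 10)),
                   list(feature_table(m / rowSums(m), mode = "relative")))
  })
  aug2 <- augment_training(train_ids, train_labels, small_donor, factor = 5,
                           seed = 1)
  expect_equal(length(aug2$ids), 25)
  # factor = 1 adds nothing
  expect_length(augment_training(train_ids, train_labels, donor_big,
                                 factor = 1, seed = 1)$ids, 0)
  # augmenting with the evaluated cohort itself is a leakage error
  expect_error(augment_training(train_ids, train_labels, donor_big,
                                target_cohort_id = donor_big$cohort_id),
               "leak")
  # the augmenting cohort is ineligible for evaluation in its stratum
  expect_setequal(eligible_cohorts(world$cohorts, "augment",
                                   augmenting_id = "SIM02"),
                  c("SIM01", "SIM03"))
  # augmented ids never reach validation folds of an augmented run
  ev <- run_nested_cv(world$cohorts[[1]], algorithm = "rf", n_iter = 2,
                      repetitions = 2, outer_k_max = 3, seed = 12,
                      importance = FALSE,
                      augment = list(dataset = donor_big, factor = 5))
  expect_gt(length(ev$augmented_ids), 0)
  expect_length(intersect(ev$augmented_ids, ev$predictions$sample_id), 0)
  expect_error(run_nested_cv(world$cohorts[[1]], augment =
                               list(dataset = world$cohorts[[1]])),
               "must differ")
})

test_that("pipeline search tunes the route and degenerates to plain nested CV", {
  world <- small_world(n_cohorts = 1, n = 100, n_taxa = 12, effect = 2,
                       seed = 53)
  ds <- attach_noise_route(world$cohorts[[1]], n_features = 12, seed = 2)
  ps <- pipeline_search(ds, algorithm = "rf", n_iter = 4, repetitions = 2,
                        outer_k_max = 4, seed = 14)
  expect_true(ps$pipeline_search)
  expect_true(all(ps$chosen$route %in% routes_of(ds)))
  # the signal-bearing genera route dominates the chosen routes
  expect_gte(mean(ps$chosen$route == "synthetic:genera"), 0.7)
  # single route: bit-identical to run_nested_cv at the same seed
  plain <- run_nested_cv(ds, route = "synthetic:genera", algorithm = "rf",
                         n_iter = 4, repetitions = 2, outer_k_max = 4,
                         seed = 14, importance = FALSE, keep_models = FALSE)
  single <- pipeline_search(ds, routes = "synthetic:genera", algorithm = "rf",
                            n_iter = 4, repetitions = 2, outer_k_max = 4,
                            seed = 14, keep_models = FALSE)
  expect_identical(plain$predictions, single$predictions)
  expect_identical(plain$auc_rep, single$auc_rep)
  # fold plans equal between plain and pipeline-search runs
  expect_identical(plain$fold_plans[[1]]$outer, ps$fold_plans[[1]]$outer)
  # mismatched samples across routes are rejected
  ds_bad <- ds
  ds_bad$tables[[2]]$sample_ids <- rev(ds_bad$tables[[2]]$sample_ids)
  rownames(ds_bad$tables[[2]]$values) <- ds_bad$tables[[2]]$sample_ids
  expect_error(pipeline_search(ds_bad, algorithm = "rf", n_iter = 2,
                               repetitions = 1, seed = 1),
               "different samples")
})

test_that("strategy comparison tabulates strategies by cohort with exclusions", {
  world <- small_world(n_cohorts = 3, n = 50, n_taxa = 8, seed = 71)
  cmp <- compare_strategies(world$cohorts,
                            strategies = c("within", "ensemble", "augment"),
                            algorithm = "rf", augmenting_id = "SIM03",
                            n_iter = 2, repetitions = 1, outer_k_max = 3,
                            seed = 31)
  expect_setequal(unique(cmp$strategy), c("within", "ensemble", "augment"))
  expect_setequal(cmp$cohort_id[cmp$strategy == "within"],
                  c("SIM01", "SIM02", "SIM03"))
  # the augmenting cohort is not evaluated under augmenting
  expect_setequal(cmp$cohort_id[cmp$strategy == "augment"],
                  c("SIM01", "SIM02"))
  expect_true(all(cmp$auc_mean >= 0 & cmp$auc_mean <= 1))
})
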