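test_that("fold planning honours the class-constraint rule", {
  plan_for <- function(n_pos, n_neg) {
    plan_folds(rep(c("caesarean", "vaginal"), c(n_pos, n_neg)))
  }
  for (case in list(c(8, 43, 8, 7), c(11, 37, 10, 9), c(10, 52, 10, 9),
                    c(159, 326, 10, 10), c(12, 40, 10, 10))) {
    p <- plan_for(case[1], case[2])
    expect_equal(p$outer_k, case[3])
    expect_equal(p$inner_k, case[4])
  }
  expect_error(plan_for(1, 30), ">= 2 samples")
})

test_that("fold assignments stratify, partition and depend only on (labels, seed, rep)", {
  y <- rep(c("caesarean", "vaginal"), c(25, 75))
  p <- plan_folds(y, outer_k_max = 10, seed = 3, repetition = 2)
  # partition
  expect_setequal(unique(p$outer), 1:10)
  expect_length(p$outer, 100)
  # every outer fold holds both classes
  for (f in 1:10) {
    expect_true(all(table(y[p$outer == f]) >= 1))
    inner <- p$inner[[f]]
    expect_setequal(inner$idx, which(p$outer != f))
    for (g in seq_len(p$inner_k)) {
      expect_true(all(table(y[inner$idx[inner$fold == g]]) >= 1))
    }
  }
  # determinism and repetition separation
  expect_identical(p, plan_folds(y, 10, seed = 3, repetition = 2))
  expect_false(identical(p$outer, plan_folds(y, 10, 3, repetition = 3)$outer))
  expect_false(identical(p$outer, plan_folds(y, 10, 4, repetition = 2)$outer))
})

test_that("roc_auc equals the brute-force pair count and handles ties", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2)), 0.75)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
  withr::with_seed(17, {
    for (i in 1:200) {
      n <- sample(4:50, 1)
      y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
      s <- sample(round(runif(n), 2))  # rounded scores force ties
      expect_equal(roc_auc(y, s), auc_bruteforce(y, s), tolerance = 1e-12)
    }
  })
})

test_that("pr_auc follows the average-precision sum with prevalence baseline", {
  expect_equal(pr_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(pr_auc(c(1, rep(0, 9)), seq(1, 0.1, by = -0.1)), 1)
  expect_error(pr_auc(c(0, 0), c(0.1, 0.2)), "at least one positive")
  withr::with_seed(23, {
    y <- rbinom(10000, 1, 0.3)
    s <- runif(10000)
    expect_equal(pr_auc(y, s), 0.3, tolerance = 0.03)
  })
})

test_that("permutation importance is zero for inert features and ~0.5 for a perfect separator", {
  # scorer that reads only feature 1
  scorer <- function(x) x[, 1]
  withr::with_seed(31, {
    n <- 100
    y <- rep(c(1, 0), each = n / 2)
    x <- cbind(f1 = y + 0, f2 = rnorm(n), f3 = 1)
    rownames(x) <- paste0("s", 1:n)
  })
  rep1 <- permutation_importance(scorer, x, y, n_shuffles = 200, seed = 5)
  expect_equal(rep1$mean_reduction[rep1$feature == "f3"], 0)  # constant
  expect_equal(rep1$mean_reduction[rep1$feature == "f2"], 0)  # ignored
  expect_equal(rep1$mean_reduction[rep1$feature == "f1"], 0.5,
               tolerance = 0.07)
  expect_identical(rep1, permutation_importance(scorer, x, y,
                                                n_shuffles = 200, seed = 5))
  # a model trained with a feature zeroed out ignores it exactly
  sep <- separable_xy(n = 60)
  xz <- sep$x; xz[, "f2"] <- 0
  cfg <- sample_candidates(default_space("rf"), 1, seed = 2)[[1]]
  m <- fit_candidate(cfg, xz, sep$y, seed = 3)
  repm <- permutation_importance(m, xz, sep$y, n_shuffles = 3, seed = 1)
  expect_equal(repm$mean_reduction[repm$feature == "f2"], 0)
  expect_error(permutation_importance(scorer, x, rep(1, n)), "both classes")
})

test_that("aggregate_importance averages reports and ranks without gaps", {
  r1 <- microcross:::new_importance_report(c("a", "b", "c"),
                                           c(0.3, 0.1, 0.2), c(0, 0, 0))
  expect_identical(aggregate_importance(list(r1, r1))$mean_reduction,
                   r1$mean_reduction)
  expect_equal(aggregate_importance(list(r1, r1))$sd_reduction, rep(0, 3))
  r2 <- microcross:::new_importance_report(c("a", "b", "c"),
                                           -c(0.3, 0.1, 0.2), c(0, 0, 0))
  agg <- aggregate_importance(list(r1, r2))
  expect_equal(agg$mean_reduction, rep(0, 3))
  expect_setequal(agg$rank, 1:3)  # ties broken by feature id, no gaps
  expect_identical(agg$rank[order(agg$feature)], 1:3)
  r3 <- microcross:::new_importance_report(c("a", "b"), c(1, 2), c(0, 0))
  expect_error(aggregate_importance(list(r1, r3)), "different feature sets")
})

test_that("nested CV recovers a strong marker and covers samples once per repetition", {
  world <- small_world(n_cohorts = 1, n = 120, n_taxa = 20, effect = 2,
                       seed = 61)
  ds <- world$cohorts[[1]]
  ev <- run_nested_cv(ds, algorithm = "rf", n_iter = 4, repetitions = 2,
                      outer_k_max = 4, seed = 9)
  expect_gte(ev$auc_mean, 0.85)
  # pooled outer-fold predictions cover each sample exactly once per rep
  for (r in 1:2) {
    ids <- ev$predictions$sample_id[ev$predictions$repetition == r]
    expect_setequal(ids, ds$tables[[1]]$sample_ids)
    expect_equal(anyDuplicated(ids), 0)
  }
  expect_equal(nrow(ev$chosen), 2 * 4)
  expect_equal(ev$auc_sd, sd(ev$auc_rep))
  # marker tops the aggregated importance
  expect_equal(ev$importance$feature[ev$importance$rank == 1],
               world$truth$marker_ids)
})

test_that("the marker leads the importance ranking in most repetitions", {
  world <- small_world(n_cohorts = 1, n = 120, n_taxa = 20, effect = 2,
                       seed = 77)
  ds <- world$cohorts[[1]]
  firsts <- vapply(1:5, function(r) {
    ev <- run_nested_cv(ds, algorithm = "rf", n_iter = 3, repetitions = 1,
                        outer_k_max = 4, seed = 100 + r)
    ev$importance$feature[ev$importance$rank == 1] == world$truth$marker_ids
  }, TRUE)
  expect_gte(sum(firsts), 4)
})

test_that("fold plans are identical across algorithms and blind to features", {
  world <- small_world(n_cohorts = 1, n = 60, n_taxa = 10, seed = 5)
  ds <- world$cohorts[[1]]
  ev_rf <- run_nested_cv(ds, algorithm = "rf", n_iter = 2, repetitions = 1,
                         outer_k_max = 4, seed = 2, importance = FALSE)
  ev_lgbm <- run_nested_cv(ds, algorithm = "lgbm", n_iter = 2, repetitions = 1,
                           outer_k_max = 4, seed = 2, importance = FALSE)
  expect_identical(ev_rf$fold_plans[[1]]$outer, ev_lgbm$fold_plans[[1]]$outer)
  # feature values never reach the planner
  scrambled_features <- ds
  scrambled_features$tables[[1]]$values <-
    ds$tables[[1]]$values[, sample(ncol(ds$tables[[1]]$values))]
  expect_identical(plan_folds(ds$labels, 4, 2, 1),
                   plan_folds(scrambled_features$labels, 4, 2, 1))
})

test_that("scrambled labels yield chance-level nested CV performance", {
  world <- small_world(n_cohorts = 1, n = 60, n_taxa = 20, effect = 2,
                       seed = 123)
  hits <- 0
  for (i in 1:20) {
    ds <- scramble_labels(world$cohorts[[1]], seed = i)
    ev <- run_nested_cv(ds, algorithm = "rf", n_iter = 4, repetitions = 1,
                        outer_k_max = 4, seed = 500 + i, importance = FALSE,
                        keep_models = FALSE)
    if (ev$auc_mean > 0.7) hits <- hits + 1
  }
  expect_lte(hits, 1)
})
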