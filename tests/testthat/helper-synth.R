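# Small in-code fixtures shared across test files.

# A tiny, quick-to-simulate multi-cohort world for unit tests.
small_world <- function(n_cohorts = 2, n = 80, n_taxa = 20, effect = 2,
                        seed = 11, ...) {
  generate_multicohort(synthetic_spec(
    n_cohorts = n_cohorts, samples_per_cohort = n, n_taxa = n_taxa,
    effect_size = effect, seed = seed, ...))
}

# A linearly separable two-class cohort for smoke fits: one informative
# feature, wide margin. Holdout sets use a smaller sd so that any decision
# threshold inside the training margin (tree splits sit at cluster edges,
# not mid-gap) still ranks them perfectly.
separable_xy <- function(n = 60, p = 5, seed = 42, sd = 0.3) {
  withr::with_seed(seed, {
    y <- rep(c("caesarean", "vaginal"), length.out = n)
    x <- matrix(rnorm(n * p), n, p, dimnames = list(
      paste0("s", seq_len(n)), paste0("f", seq_len(p))))
    x[, 1] <- ifelse(y == "caesarean", 1, 0) * 4 + rnorm(n, sd = sd)
    list(x = x, y = as_delivery_mode(y))
  })
}

# A hand-rollable best_model_spec whose "models" are plain scoring
# functions (predict_proba dispatches on functions).
fn_donor <- function(id, fns) {
  structure(list(cohort_id = id, algorithm = "rf", route = "synthetic:genera",
                 auc_mean = NA_real_, models = fns),
            class = "best_model_spec")
}

# Brute-force all-pairs AUC oracle (ties counted 1/2), independent of the
# rank-based implementation.
auc_bruteforce <- function(labels, scores) {
  y <- as.integer(labels)
  pos <- scores[y == 1]; neg <- scores[y == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# The heavy cross-study scenario used by the acceptance suite: built once,
# memoized for the whole test run. Conditions: 4 cohorts of 300 samples,
# one shared marker taxon, effect 2, batch SD 0.5; nested CV with 5
# repetitions, 10 search iterations, up to 5 folds.
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_world <- function() {
  if (!is.null(.acceptance_cache$world)) return(.acceptance_cache$world)
  sim <- generate_multicohort(synthetic_spec(seed = 20240601))
  evals <- lapply(sim$cohorts, function(ds) {
    run_nested_cv(ds, algorithm = "rf", n_iter = 10, repetitions = 5,
                  outer_k_max = 5, seed = 101, importance_reps = 1)
  })
  donors_for <- function(cid) {
    lapply(evals[setdiff(names(evals), cid)],
           function(e) select_best_model(list(e)))
  }
  ensembles <- lapply(names(sim$cohorts), function(cid) {
    cross_study_predict(sim$cohorts[[cid]], donors_for(cid), seed = 101,
                        repetitions = 5, outer_k_max = 5)
  })
  names(ensembles) <- names(sim$cohorts)
  ens_imp <- ensemble_importance(sim$cohorts[[1]], donors_for(names(sim$cohorts)[1]),
                                 n_shuffles = 3, seed = 7)
  .acceptance_cache$world <- list(sim = sim, evals = evals,
                                  ensembles = ensembles, ens_imp = ens_imp)
  .acceptance_cache$world
}
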