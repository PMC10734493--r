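#!/usr/bin/env Rscript
# Stage 3: within-study nested cross-validation, one model per cohort.
#
# Random forest with randomized hyperparameter search inside the inner
# loop. Sizes here are the analysis defaults for a laptop-scale rerun
# (5 repetitions, 10 search iterations, up to 5 folds); the full protocol
# uses 40/40/10 (see mc_defaults()).

library(microcross)

root_seed <- 20240601
cv_seed <- 101
dir.create("results", showWarnings = FALSE)

sim <- generate_multicohort(synthetic_spec(seed = root_seed))

evals <- lapply(sim$cohorts, function(ds) {
  ev <- run_nested_cv(ds, algorithm = "rf", n_iter = 10, repetitions = 5,
                      outer_k_max = 5, seed = cv_seed, importance_reps = 1)
  print(ev)
  ev
})

auc_tab <- do.call(rbind, lapply(evals, function(e) data.frame(
  cohort_id = e$cohort_id, algorithm = e$algorithm,
  auc_mean = round(e$auc_mean, 3), auc_sd = round(e$auc_sd, 3),
  pr_auc_mean = round(e$pr_auc_mean, 3), pr_auc_sd = round(e$pr_auc_sd, 3))))
utils::write.table(auc_tab, "results/within_study_auc.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

imp_tab <- do.call(rbind, lapply(evals, function(e) {
  top <- e$importance[order(e$importance$rank)[1:5], ]
  data.frame(cohort_id = e$cohort_id, top, row.names = NULL)
}))
utils::write.table(imp_tab, "results/within_study_importance.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("\nTop importance feature per cohort (truth marker:",
    sim$truth$marker_ids, "):\n")
print(imp_tab[imp_tab$rank == 1, c("cohort_id", "feature", "mean_reduction")])
saveRDS(evals, "results/within_study_evals.rds")  # reused by stages 4-5
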