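---
title: "Cross-study machine learning for multi-cohort microbiome classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-study machine learning for multi-cohort microbiome classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microcross)
```

## The problem

Gut microbiome profiles are compositional, high-dimensional and noisy, and
every cohort carries its own technical and demographic signature. Pooling
cohorts for classical hypothesis tests is therefore fragile. An
alternative is to train a classifier per cohort under a rigorous
cross-validation protocol and then ask whether what the models learned
*transfers*: can models trained on all other cohorts classify a held-out
cohort's samples? `microcross` implements that workflow for a binary host
trait — delivery mode (Caesarean vs vaginal) predicted from infant stool
16S genus tables — together with a synthetic multi-cohort generator so
that every stage can be validated against a known ground truth.

## The evaluation protocol

### Stratified nested cross-validation with a class constraint

Model performance is estimated by nested cross-validation: an outer loop
estimates generalization, and hyperparameters are tuned only inside an
inner loop over each outer-training set, so no validation sample ever
influences model selection. Both loops aim for 10 folds. Because every
fold must contain at least one sample of each class (otherwise a ROC
curve is undefined on it), with `m` minority-class samples the fold
counts are reduced to

- `outer_k = min(10, m)`
- `inner_k = min(10, floor(m * (outer_k - 1) / outer_k))`

which yields 8/7 folds for a cohort with 8 minority samples, 10/9 for 10
or 11, and the full 10/10 from 12 upwards. The second expression equals
`m - ceiling(m / outer_k)`, the worst-case minority count of an
outer-training set, so the inner constraint holds in every fold. This
reduction rule is our reconstruction from the published fold counts of
small cohorts; the package treats it as a single documented formula
rather than a lookup table.

Fold assignment is stratified (per class, shuffle then deal cyclically)
and is a function of the labels, the root seed and the repetition index
*only*. Algorithms, routes and feature values never reach the planner.
This is the seeding contract that makes AUCs comparable across
algorithms and between within-study and cross-study evaluations: they
are always computed on identical validation samples.

Per repetition, the outer-fold predictions are pooled before computing
ROC and PR AUC, and means/SDs are taken across repetitions. We pool
rather than average per-fold AUCs because validation folds in small
cohorts hold roughly five samples, where a per-fold AUC is close to
degenerate. The headline protocol uses 40 repetitions and 40 randomized
search iterations (`mc_defaults()`); the analyses and tests in this
package run scaled-down versions (typically 5 repetitions, 10
iterations, up to 5 folds, cohorts of 300 samples over 60 taxa), chosen
once as the package's reference problem sizes.

### The model zoo

Four classifier families are tuned over the hyperparameters named in
their scikit-learn incarnations:

| algorithm | backend | tuned parameters |
|---|---|---|
| `rf` | `ranger` probability forest | `max_depth`, `max_features`, `class_weight`, `bootstrap` |
| `extra` | `ranger`, `splitrule = "extratrees"`, no resampling | `max_depth`, `max_features`, `class_weight` |
| `lgbm` | `xgboost`, `grow_policy = "lossguide"` | `num_leaves`, `max_depth`, `n_estimators`, `reg_alpha`, `learning_rate` |
| `mlp` | built-in (`mlp_fit()`) | `hidden_layer_sizes`, `max_iter`, `alpha`, `learning_rate_init`, `momentum` |

Candidate values (see `default_space()`) are package defaults spanning
standard ranges — `max_depth` in {2, 4, 8, 16, unlimited}, regularization
and learning rates log-uniform, etc. — and every grid can be overridden.
Forests default to 100 trees, the scikit-learn default, since tree count
is not a tuned parameter in this protocol; it is exposed as `num_trees`.
MLP architectures follow a halving rule: first layers of 10/30/50/100
units, depths 1–3, each subsequent layer half the width of the previous
one (12 architectures). The MLP is a deliberately minimal in-package
implementation (ReLU, sigmoid output, full-batch adam, Glorot
initialization, standardized inputs) because no installed R package
offers a multi-hidden-layer perceptron with these named knobs; its
`momentum` maps to adam's `beta1` so that the parameter stays active
under the adam solver. Leaf-wise `xgboost` stands in for the
light-gradient-boosting family: `num_leaves` maps to `max_leaves` under
`grow_policy = "lossguide"`, `reg_alpha` to `alpha`, `n_estimators` to
`nrounds`.

Randomized search draws `n_iter` candidates per outer fold, scores each
by mean inner-fold ROC AUC, and refits the winner (ties: first in
sampled order) on the outer-training set.

### Permutation importance

Feature importance is the drop in test-fold AUC when one feature's
column is permuted across the test samples, averaged over `n_shuffles`
permutations (default 5 per fold; tight-tolerance checks use 200).
Reports are averaged across folds and repetitions, and features are
ranked by mean AUC reduction (ties broken by feature id). A feature that
is constant in the test fold, or that the model ignores, has importance
exactly 0 by construction. Permuted copies are batched into large
prediction calls because forest backends pay per-call overhead.

## Cross-cohort strategies

**Leave-one-cohort-out ensemble.** Each donor cohort contributes its
best within-study model family (argmax of mean AUC; exact ties resolved
by the fixed precedence `rf < extra < lgbm < mlp`, then genera before
pathways). A donor's prediction is the mean probability of its
repetition-1 outer-fold refits; the ensemble averages donors with equal
weight. We keep one repetition's fold refits per donor rather than a
single whole-cohort refit — the fold models are exactly the models the
within-study step validated — and we average probabilities rather than
votes. Target labels enter only the AUC computation, never the scoring.
Feature spaces are harmonized by reindexing the target table onto each
donor model's training features, zero-filling absent taxa
(union-style alignment, `align_features()`); relative abundances are not
renormalized after zero-filling since only zeros are added. How the
original protocol harmonized taxa across cohorts is not recorded, so
union alignment is this package's own choice: it preserves every donor
model's feature expectations at the cost of scoring structurally absent
taxa as zeros.

**Control augmenting.** Training folds are enriched with control-class
(vaginal) samples from a designated external cohort until the fold's
control count is raised `factor`-fold (default 5), drawing without
replacement and exhausting the donor if it is too small. Inner folds
partition the *original* outer-training samples; augmented controls are
appended to inner-training sets and to the final refit only, so no
augmented sample ever sits in an inner or outer validation fold. The
augmenting cohort itself is excluded from model building and cross-study
validation in its stratum (`eligible_cohorts()`), because its samples
would otherwise appear in other cohorts' training data while being
validated on.

**Pipeline search.** Preprocessing choices (taxonomy database, genera vs
predicted-pathway feature space) are treated as one categorical
hyperparameter: each candidate draws a route uniformly alongside its
hyperparameters, inner-loop scoring and the final refit use the
candidate's route, and the chosen route per outer fold is recorded.
Routes are drawn from a dedicated seed stream *after* the
hyperparameters, so a single-route search is bit-for-bit identical to
the plain engine — a property the test suite asserts.

## The synthetic multi-cohort generator

`generate_multicohort()` draws, for cohort `c`, sample `i`, taxon `t`:

```
log_abundance = baseline(t) + batch_c(t)
              + effect_size * [t is a marker] * [sample in effect class]
              + Normal(0, noise_sd)
```

with proportions the row-wise softmax and counts multinomial at a depth
uniform in `depth_range`. A log-normal-softmax model was preferred over
a plain Dirichlet-multinomial because it gives independent control of
the batch and class effects on the log scale. The baseline is drawn once
per run from `Normal(0, 1.5)` with one non-marker taxon raised by +2,
mimicking the skewed rank-abundance of the infant gut without fitting
any real data.

Defaults — the package's reference study conditions, fixed once — are 4
cohorts of 300 samples (the scale of real infant cohorts, 48–485),
caesarean fraction 0.3 (the observed 1–2-month prevalence is ~30%), 60
taxa (genus counts after standard filtering are of order 50–150),
`effect_size = 2` and `noise_sd = 0.5` (a strong but not trivial marker:
a single-threshold classifier on the marker reaches AUC ≈ 0.95 within a
cohort), `batch_sd = 0.5`, depths 1,000–50,000. The marker is enriched
in the *vaginal* class by default, following the direction stated for
*Bacteroides* at 1–2 months in the delivery-mode literature; the
reported direction is not fully consistent across sources, so
`effect_class` is a parameter rather than a constant.

What the generator does **not** emulate: phylogenetic correlation among
taxa, longitudinal structure across age strata, zero-inflation beyond
what softmax + multinomial induce, and realistic absolute diversity
levels (simulated Shannon indices run higher than real 1–2-month
infant samples). Passing the recovery suites therefore shows the
*machinery* is sound — signal present implies signal found, signal
absent implies chance-level AUC — not that real-data AUCs would match.

Supporting fixtures: `derive_pathway_route()` builds a second feature
space as a fixed non-negative linear mix of the genus proportions
(shared across cohorts for a given seed), so pathway tables inherit
signal the way predicted metabolic pathways do; `attach_noise_route()`
builds an independent no-signal route for route-selection experiments;
`scramble_labels()` is the null fixture.

## Numerical and degenerate-input conventions

- Shannon diversity is reported in bits (base-2 logarithm, the
  q2-diversity convention); zero proportions contribute zero.
- Rarefying samples without replacement (multivariate hypergeometric)
  and drops samples below the chosen depth; the depth rule is "at least
  1,000 reads, then the smallest per-sample total that loses no further
  sample".
- Bray–Curtis matrices come from `vegan::vegdist` and are cross-checked
  against the package's own pairwise formula; PCoA is classical scaling
  via `cmdscale` with eigenvalues ≤ 1e-10 truncated (negative,
  non-Euclidean axes are dropped, not corrected — the ordination is
  descriptive here) and a deterministic sign convention (first nonzero
  loading of each axis positive).
- Kruskal–Wallis on fully tied data returns H = 0, p = 1 (the
  tie-correction denominator vanishes, but all mean ranks are equal by
  construction). Delivery-mode diversity comparisons run per cohort,
  with Benjamini–Hochberg adjustment across the cohorts of a stratum;
  the alternative (pooling cohorts per stratum) would conflate batch
  and class effects.
- ROC AUC uses the midrank (Mann–Whitney) formulation, exact under
  ties; PR AUC is the step-wise average-precision sum over distinct
  thresholds. Both are validated against brute-force oracles.
- All randomness derives from one root seed through named streams keyed
  by `(purpose, cohort, repetition, fold)` (`seed_stream()`), so adding
  an algorithm or diagnostic never perturbs fold plans or simulated
  data, and any draw can be reproduced in isolation.
- Relative-mode tables must have rows summing to 1 within 1e-9;
  all-zero samples are rejected rather than silently renormalized.

## Known limitations

- Donor ensembles reuse repetition-1 fold refits; repetitions of
  `cross_study_predict()` therefore differ only in fold bookkeeping, and
  its SD over repetitions is 0 by construction under a fixed donor set.
- The gradient-boosting family is leaf-wise `xgboost`, not LightGBM;
  small numerical differences from a LightGBM implementation are
  expected even at identical named hyperparameters.
- The MLP is full-batch; very large cohorts would warrant minibatching.
- No UniFrac (the generator has no phylogeny) and no figure rendering:
  outputs are tidy TSV/JSON tables, plotted by the user's tool of
  choice.
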