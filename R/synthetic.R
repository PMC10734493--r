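#' Specification for the multi-cohort simulator
#'
#' Defines the generative model used throughout the test suite and the
#' analysis scripts: a log-normal-softmax compositional model with a
#' cohort-level batch effect and a delivery-mode effect concentrated on one
#' or a few marker taxa (a *Bacteroides*-like signature).
#'
#' For cohort `c`, sample `i` of class `y` the taxon log-abundance is
#' `baseline(t) + batch_c(t) + effect_size * 1[t in markers, y in
#' effect_class] + Normal(0, noise_sd)`; proportions are the softmax of that
#' vector, and counts are multinomial at a depth drawn uniformly from
#' `depth_range`.
#'
#' Defaults encode the study conditions the package emulates: cohorts of
#' 300 samples with ~30% Caesarean deliveries over 60 genus-level taxa, a
#' single marker taxon enriched in the vaginal class on the log scale
#' (`effect_size = 2`), cohort batch shifts (`batch_sd = 0.5`) and
#' per-sample dispersion (`noise_sd = 0.5`), sequencing depths
#' 1,000-50,000.
#'
#' @param n_cohorts number of cohorts (>= 1).
#' @param samples_per_cohort integer vector, one entry per cohort (a single
#'   value is recycled).
#' @param caesarean_fraction fraction of Caesarean (positive-class) samples
#'   per cohort, in (0, 1).
#' @param n_taxa number of taxa (>= 5).
#' @param marker_indices indices (1-based) of the taxa carrying the class
#'   effect.
#' @param effect_size log-scale shift applied to marker taxa in the
#'   `effect_class` (>= 0).
#' @param effect_class class in which markers are shifted up;
#'   `"vaginal"` (default, marker enriched in vaginally delivered infants)
#'   or `"caesarean"`.
#' @param batch_sd SD of per-cohort, per-taxon log-scale shifts (>= 0).
#' @param noise_sd SD of per-sample log-scale dispersion (> 0).
#' @param depth_range `c(min, max)` counts for multinomial sampling;
#'   `min >= 100`.
#' @param seed integer root seed for the generator.
#' @return a `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_cohorts = 4,
                           samples_per_cohort = 300,
                           caesarean_fraction = 0.3,
                           n_taxa = 60,
                           marker_indices = 1,
                           effect_size = 2,
                           effect_class = c("vaginal", "caesarean"),
                           batch_sd = 0.5,
                           noise_sd = 0.5,
                           depth_range = c(1000L, 50000L),
                           seed = 1) {
  effect_class <- match.arg(effect_class)
  if (length(samples_per_cohort) == 1)
    samples_per_cohort <- rep(samples_per_cohort, n_cohorts)
  stopifnot(n_cohorts >= 1, length(samples_per_cohort) == n_cohorts,
            caesarean_fraction > 0, caesarean_fraction < 1,
            n_taxa >= 5, effect_size >= 0, batch_sd >= 0, noise_sd > 0,
            length(depth_range) == 2, depth_range[1] >= 100,
            depth_range[1] <= depth_range[2])
  marker_indices <- as.integer(marker_indices)
  if (any(marker_indices < 1 | marker_indices > n_taxa))
    stop("marker_indices out of 1..n_taxa", call. = FALSE)
  n_pos <- round(caesarean_fraction * samples_per_cohort)
  if (any(n_pos < 2 | samples_per_cohort - n_pos < 2))
    stop("caesarean_fraction leaves < 2 samples of a class in some cohort",
         call. = FALSE)
  structure(list(n_cohorts = as.integer(n_cohorts),
                 samples_per_cohort = as.integer(samples_per_cohort),
                 caesarean_fraction = caesarean_fraction,
                 n_taxa = as.integer(n_taxa),
                 marker_indices = marker_indices,
                 effect_size = effect_size, effect_class = effect_class,
                 batch_sd = batch_sd, noise_sd = noise_sd,
                 depth_range = as.integer(depth_range), seed = seed),
            class = "synthetic_spec")
}

#' Generate synthetic multi-cohort feature tables with known ground truth
#'
#' Draws the model of [synthetic_spec()]: a shared baseline rank-abundance
#' profile (log-abundances `Normal(0, 1.5)` with one non-marker taxon
#' raised by +2 to mimic the dominance structure of the infant gut),
#' per-cohort batch shifts, the class effect on the marker taxa, and
#' per-sample noise. Each cohort receives both a counts table and a
#' relative table under route `synthetic:genera`. Deterministic given
#' `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with elements
#'   \item{cohorts}{named list of [cohort_dataset()]s (`SIM01`, `SIM02`, ...),
#'     each holding the relative table under route `synthetic:genera` plus a
#'     counts table in `$counts`;}
#'   \item{truth}{list with the labels, marker indices, effect size and
#'     per-cohort batch shift matrix actually used.}
#' @export
generate_multicohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  taxa <- sprintf("g%03d", seq_len(spec$n_taxa))
  baseline <- with_stream(spec$seed, "baseline", code = {
    b <- stats::rnorm(spec$n_taxa, 0, 1.5)
    dominant <- sample(setdiff(seq_len(spec$n_taxa), spec$marker_indices), 1)
    b[dominant] <- b[dominant] + 2
    b
  })
  batch <- with_stream(spec$seed, "batch", code = {
    matrix(stats::rnorm(spec$n_cohorts * spec$n_taxa, 0, spec$batch_sd),
           spec$n_cohorts, spec$n_taxa)
  })
  cohorts <- vector("list", spec$n_cohorts)
  truth_labels <- vector("list", spec$n_cohorts)
  for (c_i in seq_len(spec$n_cohorts)) {
    n <- spec$samples_per_cohort[c_i]
    cid <- sprintf("SIM%02d", c_i)
    n_pos <- round(spec$caesarean_fraction * n)
    labels <- with_stream(spec$seed, "labels", cid, code = {
      sample(rep(c("caesarean", "vaginal"), c(n_pos, n - n_pos)))
    })
    labels <- as_delivery_mode(labels)
    shift <- rep(0, spec$n_taxa)
    shift[spec$marker_indices] <- spec$effect_size
    logab <- with_stream(spec$seed, "abund", cid, code = {
      la <- matrix(stats::rnorm(n * spec$n_taxa, 0, spec$noise_sd),
                   n, spec$n_taxa)
      la <- sweep(la, 2, baseline + batch[c_i, ], "+")
      in_class <- labels == spec$effect_class
      la[in_class, ] <- sweep(la[in_class, , drop = FALSE], 2, shift, "+")
      la
    })
    # softmax per row
    rel <- exp(logab - apply(logab, 1, max))
    rel <- rel / rowSums(rel)
    counts <- with_stream(spec$seed, "depth", cid, code = {
      depths <- sample(seq(spec$depth_range[1], spec$depth_range[2]), n,
                       replace = TRUE)
      t(vapply(seq_len(n),
               function(i) stats::rmultinom(1, depths[i], rel[i, ])[, 1],
               numeric(spec$n_taxa)))
    })
    ids <- sprintf("%s_s%04d", cid, seq_len(n))
    dimnames(rel) <- dimnames(counts) <- list(ids, taxa)
    rel_t <- feature_table(rel, mode = "relative",
                           route = route_tag("synthetic", "genera"))
    cnt_t <- feature_table(counts, mode = "counts",
                           route = route_tag("synthetic", "genera"))
    ds <- cohort_dataset(cid, "m1_2", labels, list(rel_t))
    ds$counts <- cnt_t
    cohorts[[c_i]] <- ds
    truth_labels[[cid]] <- labels
  }
  names(cohorts) <- vapply(cohorts, `[[`, "", "cohort_id")
  list(cohorts = cohorts,
       truth = list(labels = truth_labels,
                    marker_indices = spec$marker_indices,
                    marker_ids = taxa[spec$marker_indices],
                    effect_size = spec$effect_size,
                    effect_class = spec$effect_class,
                    baseline = baseline, batch = batch))
}

#' Derive a synthetic "predicted pathway" route from the genera route
#'
#' Emulates a second feature space (as functional-pathway prediction does
#' for real 16S data) by multiplying the genus relative abundances with a
#' fixed non-negative random mixing matrix whose rows sum to 1, shared
#' across cohorts for a given `mixing_seed`. Because the map is linear in
#' the genus proportions, class signal carried by the genera leaks into the
#' pathway space, as it does for real predicted pathways.
#'
#' @param dataset a [cohort_dataset()] with a `synthetic:genera` route.
#' @param n_pathways number of pathway features (>= 2).
#' @param mixing_seed seed fixing the mixing matrix across cohorts.
#' @param mixing optional explicit mixing matrix (`n_taxa x n_pathways`,
#'   non-negative); overrides the random draw (test hook).
#' @return the dataset with an added `synthetic:pathways` route.
#' @export
derive_pathway_route <- function(dataset, n_pathways = 40, mixing_seed = 1,
                                 mixing = NULL) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (n_pathways < 2) stop("n_pathways must be >= 2", call. = FALSE)
  genera <- get_route(dataset, route_tag("synthetic", "genera"))
  p <- length(genera$feature_ids)
  if (is.null(mixing)) {
    mixing <- with_stream(mixing_seed, "pathway_mixing", p, n_pathways, code = {
      matrix(stats::rexp(p * n_pathways), p, n_pathways)
    })
  }
  stopifnot(is.matrix(mixing), nrow(mixing) == p, ncol(mixing) == n_pathways,
            all(mixing >= 0))
  mixing <- mixing / rowSums(mixing)
  vals <- genera$values %*% mixing
  vals <- vals / rowSums(vals)  # guard against accumulated rounding
  colnames(vals) <- sprintf("pwy%03d", seq_len(n_pathways))
  add_route(dataset, feature_table(vals, sample_ids = genera$sample_ids,
                                   mode = "relative",
                                   route = route_tag("synthetic", "pathways")))
}

#' Attach a pure-noise route carrying no class signal
#'
#' Builds an independent compositional table (log-normal softmax, no class
#' or batch effect) over the same samples and attaches it under the given
#' route. Used as the distractor arm in route-selection experiments.
#'
#' @param dataset a [cohort_dataset()].
#' @param n_features number of noise features.
#' @param seed seed for the noise draw.
#' @param route route tag for the new table (default `synthetic:pathways`).
#' @return the dataset with the noise route added.
#' @export
attach_noise_route <- function(dataset, n_features = 40, seed = 1,
                               route = route_tag("synthetic", "pathways")) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  ids <- dataset$tables[[1]]$sample_ids
  n <- length(ids)
  vals <- with_stream(seed, "noise_route", dataset$cohort_id, code = {
    la <- matrix(stats::rnorm(n * n_features, 0, 1.5), n, n_features)
    e <- exp(la - apply(la, 1, max))
    e / rowSums(e)
  })
  dimnames(vals) <- list(ids, sprintf("nz%03d", seq_len(n_features)))
  add_route(dataset, feature_table(vals, mode = "relative", route = route))
}

#' Permute a cohort's labels (null-model fixture)
#'
#' Labels are permuted uniformly at random; class counts are preserved and
#' feature tables untouched.
#'
#' @param dataset a [cohort_dataset()].
#' @param seed permutation seed.
#' @return the dataset with permuted labels.
#' @export
scramble_labels <- function(dataset, seed = 1) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  dataset$labels <- with_stream(seed, "scramble", dataset$cohort_id, code = {
    dataset$labels[sample(length(dataset$labels))]
  })
  dataset
}
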