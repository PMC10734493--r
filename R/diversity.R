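#' Choose a rarefaction depth
#'
#' Applies the two-rule policy used for cohort characterization: (i) a
#' depth of `floor` reads is the minimum admissible, and (ii) take the next
#' highest value that loses no further samples — i.e. the smallest
#' per-sample total among samples at or above the floor. Samples below the
#' floor are dropped (and reported).
#'
#' @param count_tables list of counts-mode [feature_table()]s.
#' @param floor minimum admissible depth (default 1000).
#' @return integer depth, with attribute `dropped` naming the samples whose
#'   totals fall below the floor.
#' @export
choose_rarefaction_depth <- function(count_tables, floor = 1000) {
  if (inherits(count_tables, "feature_table")) count_tables <- list(count_tables)
  stopifnot(all(vapply(count_tables, inherits, TRUE, "feature_table")))
  totals <- unlist(lapply(count_tables, function(t) {
    stats::setNames(rowSums(t$values), t$sample_ids)
  }))
  keep <- totals >= floor
  if (!any(keep))
    stop("no sample reaches the rarefaction floor of ", floor, call. = FALSE)
  depth <- as.integer(min(totals[keep]))
  attr(depth, "dropped") <- names(totals)[!keep]
  depth
}

#' Rarefy a count table to a common depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to exactly `depth`; samples whose totals fall below
#' `depth` are removed. Deterministic given `seed`.
#'
#' @param table a counts-mode [feature_table()].
#' @param depth target depth (> 0).
#' @param seed integer seed.
#' @return a counts-mode [feature_table()] whose rows all sum to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  totals <- rowSums(table$values)
  keep <- which(totals >= depth)
  if (length(keep) == 0) stop("no sample has >= depth reads", call. = FALSE)
  out <- with_stream(seed, "rarefy", depth, code = {
    t(vapply(keep, function(i) {
      x <- table$values[i, ]
      reads <- rep.int(seq_along(x), x)
      picked <- reads[sample.int(length(reads), depth)]
      tabulate(picked, nbins = length(x))
    }, numeric(ncol(table$values))))
  })
  dimnames(out) <- list(table$sample_ids[keep], table$feature_ids)
  feature_table(out, mode = "counts", route = table$route)
}

#' Shannon diversity (bits)
#'
#' `H = -sum(p * log2(p))` over positive entries of a relative-abundance
#' vector, the base-2 convention of the q2-diversity tooling.
#'
#' @param rel non-negative vector summing to 1 (within 1e-6).
#' @return Shannon index in bits.
#' @export
shannon <- function(rel) {
  stopifnot(is.numeric(rel), all(rel >= 0))
  if (abs(sum(rel) - 1) > 1e-6)
    stop("relative abundances must sum to 1 (got ", format(sum(rel)), ")",
         call. = FALSE)
  p <- rel[rel > 0]
  -sum(p * log2(p))
}

#' Bray-Curtis dissimilarity between two samples
#'
#' `BC = sum(|a - b|) / sum(a + b)`; 0 for identical samples, 1 for
#' disjoint supports.
#'
#' @param a,b equal-length non-negative abundance vectors with positive sums.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(a, b) {
  stopifnot(length(a) == length(b), all(a >= 0), all(b >= 0))
  if (sum(a) == 0 || sum(b) == 0)
    stop("Bray-Curtis undefined for zero-sum samples", call. = FALSE)
  sum(abs(a - b)) / sum(a + b)
}

#' Bray-Curtis distance matrix for a feature table
#'
#' Computed with `vegan::vegdist(method = "bray")`, returned as a
#' `distance_matrix` (symmetric, zero diagonal, entries in `[0, 1]`).
#'
#' @param table a [feature_table()].
#' @return a `distance_matrix` object (list of `sample_ids` and `values`).
#' @export
bray_curtis_matrix <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  d <- as.matrix(vegan::vegdist(table$values, method = "bray"))
  diag(d) <- 0
  dimnames(d) <- list(table$sample_ids, table$sample_ids)
  structure(list(sample_ids = table$sample_ids, values = d),
            class = "distance_matrix")
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Wraps `stats::cmdscale()` on the distance matrix: eigendecomposition of
#' the double-centered squared-distance matrix. Axes with eigenvalue
#' <= 1e-10 are truncated (negative eigenvalues from non-Euclidean
#' Bray-Curtis matrices are dropped, not corrected), and each axis is
#' sign-fixed so that its first nonzero loading is positive.
#'
#' @param d a `distance_matrix` (from [bray_curtis_matrix()]) or a base
#'   `dist`/square matrix.
#' @param n_axes maximum number of axes to return (>= 1).
#' @return a `pcoa_result`: list of `coordinates` (samples x axes) and
#'   `eigenvalues` (non-increasing, all > 1e-10).
#' @export
pcoa <- function(d, n_axes = 2) {
  if (n_axes < 1) stop("n_axes must be >= 1", call. = FALSE)
  if (inherits(d, "distance_matrix")) {
    ids <- d$sample_ids
    dm <- d$values
  } else {
    dm <- as.matrix(d)
    ids <- rownames(dm)
    if (is.null(ids)) ids <- paste0("s", seq_len(nrow(dm)))
  }
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix not symmetric",
                                         call. = FALSE)
  k <- min(n_axes, nrow(dm) - 1)
  # cmdscale warns when fewer than k eigenvalues are positive; truncation
  # to positive axes is this function's documented behaviour
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = k,
                                          eig = TRUE))
  eig <- fit$eig
  keep <- which(eig[seq_len(ncol(fit$points))] > 1e-10)
  coords <- fit$points[, keep, drop = FALSE]
  # sign convention: first nonzero loading of each axis is positive
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(ids, paste0("PCo", seq_len(ncol(coords))))
  structure(list(coordinates = coords, eigenvalues = eig[keep]),
            class = "pcoa_result")
}

#' Kruskal-Wallis H-test
#'
#' Rank-based H with tie correction and a chi-square reference with
#' `k - 1` degrees of freedom, via `stats::kruskal.test()`.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return list with elements `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) == 0)) stop("empty group", call. = FALSE)
  if (sum(lengths(groups)) < 3) stop("need total n >= 3", call. = FALSE)
  # fully tied data: the tie-correction denominator vanishes; H is 0 by
  # construction (all mean ranks equal), so report that rather than NaN
  if (length(unique(unlist(groups))) == 1) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`stats::p.adjust(method = "BH")`) with input
#' validation; adjusted values are returned in input order, capped at 1.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(is.numeric(pvals), length(pvals) >= 1)
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Per-cohort delivery-mode diversity comparison within an age stratum
#'
#' For each cohort: rarefies its count table to the stratum-wide depth
#' chosen by [choose_rarefaction_depth()], computes per-sample Shannon
#' diversity, and runs a Kruskal-Wallis test between Caesarean and vaginal
#' samples; p-values are Benjamini-Hochberg-adjusted across the cohorts of
#' the stratum.
#'
#' @param cohorts named list of [cohort_dataset()]s, each with a counts
#'   table in `$counts`.
#' @param floor rarefaction floor (default 1000).
#' @param seed rarefying seed.
#' @return data frame: cohort_id, depth, n samples retained, mean Shannon
#'   per class, H, p, p_adj.
#' @export
compare_alpha_by_delivery <- function(cohorts, floor = 1000, seed = 1) {
  stopifnot(length(cohorts) >= 1)
  depth <- choose_rarefaction_depth(lapply(cohorts, `[[`, "counts"),
                                    floor = floor)
  rows <- lapply(cohorts, function(ds) {
    rar <- rarefy(ds$counts, depth, seed = seed_stream(seed, "rarefy",
                                                       ds$cohort_id))
    rel <- normalize_relative(rar)
    h <- apply(rel$values, 1, shannon)
    lab <- ds$labels[match(rar$sample_ids, ds$tables[[1]]$sample_ids)]
    kw <- kruskal_wallis(split(h, lab))
    data.frame(cohort_id = ds$cohort_id, depth = as.integer(depth),
               n = length(h),
               shannon_vaginal = mean(h[lab == "vaginal"]),
               shannon_caesarean = mean(h[lab == "caesarean"]),
               H = kw$H, p = kw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- bh_adjust(out$p)
  out
}
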