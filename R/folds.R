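#' Plan stratified nested cross-validation folds
#'
#' Both loops aim for `outer_k_max` (default 10) folds, reduced so that
#' every outer and inner fold contains at least one sample of each class —
#' the constraint that makes a ROC curve computable in every validation
#' fold. With `m` minority-class samples:
#' \itemize{
#'   \item `outer_k = min(outer_k_max, m)`
#'   \item `inner_k = min(outer_k_max, floor(m * (outer_k - 1) / outer_k))`
#' }
#' so a cohort with `m = 8` gets 8 outer / 7 inner folds, `m = 10` or
#' `m = 11` get 10 outer / 9 inner folds, and `m >= 12` the full 10/10.
#'
#' Assignment is stratified: within each class, samples are shuffled by a
#' generator seeded from `(seed, repetition)` only — never from feature
#' values, the algorithm or the route — and dealt cyclically into folds.
#' This guarantees identical outer splits for every algorithm and strategy
#' at a given seed, making their AUCs directly comparable.
#'
#' @param labels per-sample binary labels ([as_delivery_mode()] dialects).
#' @param outer_k_max maximum fold count for both loops (default 10).
#' @param seed root seed.
#' @param repetition repetition index (>= 1); distinct repetitions get
#'   independent shuffles.
#' @return a `fold_plan`: list with `repetition`, `outer_k`, `inner_k`,
#'   `outer` (per-sample outer fold index in `1..outer_k`) and `inner`
#'   (per outer fold, a list with the training-sample indices `idx` and
#'   their inner fold assignment `fold` in `1..inner_k`).
#' @export
plan_folds <- function(labels, outer_k_max = 10, seed = 1, repetition = 1) {
  y <- as_delivery_mode(labels)
  n <- length(y)
  m <- min(table(y))
  if (m < 2)
    stop("need >= 2 samples of each class to satisfy the fold constraint",
         call. = FALSE)
  outer_k <- min(outer_k_max, m)
  inner_k <- min(outer_k_max, floor(m * (outer_k - 1) / outer_k))
  outer <- integer(n)
  with_stream(seed, "folds", repetition, code = {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      outer[sample(idx)] <- rep_len(seq_len(outer_k), length(idx))
    }
  })
  inner <- vector("list", outer_k)
  for (f in seq_len(outer_k)) {
    tr <- which(outer != f)
    fold <- integer(length(tr))
    with_stream(seed, "inner", repetition, f, code = {
      for (cl in levels(y)) {
        pos <- which(y[tr] == cl)
        fold[sample(pos)] <- rep_len(seq_len(inner_k), length(pos))
      }
    })
    inner[[f]] <- list(idx = tr, fold = fold)
  }
  structure(list(repetition = repetition, outer_k = as.integer(outer_k),
                 inner_k = as.integer(inner_k), outer = outer, inner = inner),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> repetition %d: %d outer / %d inner folds over %d samples\n",
              x$repetition, x$outer_k, x$inner_k, length(x$outer)))
  invisible(x)
}
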