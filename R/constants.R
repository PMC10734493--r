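#' Default experiment constants
#'
#' The headline defaults of the cross-study workflow, collected in one place:
#' \describe{
#'   \item{outer_k_max}{maximum fold count for both cross-validation loops
#'     (10; reduced automatically for small minority classes, see
#'     [plan_folds()]).}
#'   \item{n_iter}{randomized hyperparameter search iterations (40).}
#'   \item{repetitions}{nested cross-validation repetitions over which
#'     performance and importance are averaged (40).}
#'   \item{augment_factor}{control-augmenting multiplier: training-fold
#'     control counts are raised fivefold (5).}
#'   \item{rarefaction_floor}{minimum admissible rarefaction depth (1000).}
#'   \item{n_shuffles}{per-fold shuffles for permutation importance (5).}
#'   \item{num_trees}{forest size for the tree ensembles (100).}
#' }
#'
#' @return a named list of the defaults above.
#' @export
mc_defaults <- function() {
  list(
    outer_k_max      = 10L,
    n_iter           = 40L,
    repetitions      = 40L,
    augment_factor   = 5L,
    rarefaction_floor = 1000L,
    n_shuffles       = 5L,
    num_trees        = 100L
  )
}

# canonical label levels; the positive (minority, scored) class is Caesarean
.mc_levels <- c("vaginal", "caesarean")
.mc_positive <- "caesarean"

#' Canonical class labels
#'
#' Delivery mode is modelled as a binary factor with levels
#' `c("vaginal", "caesarean")`; `"caesarean"` is the positive class (the
#' minority class in most cohorts, which keeps precision-recall curves
#' informative).
#'
#' @param x a vector of labels in any accepted dialect: factors/characters
#'   among (case-insensitive) caesarean/cesarean/cs/1 vs vaginal/vd/0, or a
#'   0/1 numeric/logical vector.
#' @return a factor with levels `c("vaginal", "caesarean")`.
#' @export
as_delivery_mode <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.logical(x)) x <- as.integer(x)
  if (is.numeric(x)) x <- as.character(x)
  key <- tolower(trimws(x))
  pos <- key %in% c("caesarean", "cesarean", "cs", "1")
  neg <- key %in% c("vaginal", "vd", "0")
  bad <- !(pos | neg)
  if (any(bad)) {
    stop("unknown class label(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  factor(ifelse(pos, .mc_positive, "vaginal"), levels = .mc_levels)
}
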