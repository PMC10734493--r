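#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive sample receives a higher score than a randomly chosen negative
#' one, with tied scores counted 1/2. Computed from midranks, so it is
#' exact under ties.
#'
#' @param labels binary labels (any dialect of [as_delivery_mode()], or a
#'   logical/0-1 vector); the positive class is `"caesarean"` / 1 / TRUE.
#' @param scores numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  y <- as_binary01(labels)
  stopifnot(length(y) == length(scores), all(is.finite(scores)))
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC needs both classes present", call. = FALSE)
  r <- rank(scores)  # midranks handle ties
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average-precision sum `AP = sum_k (R_k - R_{k-1}) P_k` over
#' the distinct score thresholds in decreasing order (tied scores form a
#' single threshold). The chance baseline equals the positive prevalence.
#'
#' @inheritParams roc_auc
#' @return average precision in `(0, 1]`.
#' @export
pr_auc <- function(labels, scores) {
  y <- as_binary01(labels)
  stopifnot(length(y) == length(scores), all(is.finite(scores)))
  n_pos <- sum(y == 1)
  if (n_pos == 0) stop("PR AUC needs at least one positive", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  grp_last <- cumsum(rle(s)$lengths)      # index of last sample per threshold
  tp <- cumsum(y)[grp_last]
  n_at <- grp_last
  precision <- tp / n_at
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

# coerce labels of any accepted dialect to 0/1 with 1 = positive class
as_binary01 <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(as.integer(labels))
  as.integer(as_delivery_mode(labels) == .mc_positive)
}
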