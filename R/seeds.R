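#' Derive a child seed from a root seed and a stream key
#'
#' All randomness in the package flows from one root seed through named
#' streams keyed by `(purpose, cohort, repetition, fold)`. Keying streams by
#' purpose rather than by draw order means that adding an algorithm, a route
#' or an extra diagnostic never perturbs fold assignments or simulated data:
#' the fold stream for repetition 3 of cohort "A" is the same integer no
#' matter what else the run computes.
#'
#' The derivation is a polynomial rolling hash (base 31) of the
#' `/`-joined key parts, reduced modulo 2^31 - 2 and shifted to `[1, 2^31-2]`
#' so it is always a valid positive integer seed.
#'
#' @param root integer root seed.
#' @param ... key parts (coerced to character), e.g. `"folds", cohort, rep`.
#' @return a positive integer seed, deterministic in `root` and the key.
#' @examples
#' seed_stream(1, "folds", "NOMIC", 3)
#' @export
seed_stream <- function(root, ...) {
  stopifnot(is.numeric(root), length(root) == 1, is.finite(root))
  key <- paste(c(format(root, scientific = FALSE), as.character(list(...))),
               collapse = "/")
  m <- 2147483647  # 2^31 - 1, prime
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% m
  # avoid 0; keep strictly below 2^31 - 1
  as.integer(h %% (m - 2L) + 1L)
}

#' Evaluate code with a derived seed, restoring the RNG state afterwards
#'
#' @param root,... as [seed_stream()].
#' @param code code to evaluate.
#' @keywords internal
with_stream <- function(root, ..., code) {
  withr::with_seed(seed_stream(root, ...), code)
}
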