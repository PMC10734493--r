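#' Minimal multilayer perceptron for binary classification
#'
#' A small, dependency-free feed-forward network: ReLU hidden layers, a
#' sigmoid output unit, binary cross-entropy loss with an L2 penalty
#' `alpha * ||W||^2 / (2n)`, trained full-batch with the adam update rule.
#' Glorot-uniform initialization from a dedicated seed makes training
#' deterministic. Inputs are standardized internally (centre/scale stored
#' with the fit).
#'
#' The tunable `momentum` is mapped to adam's first-moment decay `beta1`,
#' so the parameter remains active under the adam solver.
#'
#' @param x training matrix (samples x features).
#' @param y binary labels ([as_delivery_mode()] dialects).
#' @param hidden integer vector of hidden-layer widths, e.g. `c(50, 25)`.
#' @param max_iter number of full-batch epochs.
#' @param alpha L2 penalty strength.
#' @param learning_rate_init adam step size.
#' @param momentum adam `beta1`.
#' @param seed initialization seed.
#' @return an `mlp_fit` object for [mlp_predict()].
#' @export
mlp_fit <- function(x, y, hidden = c(30L, 15L), max_iter = 200L,
                    alpha = 1e-4, learning_rate_init = 1e-3,
                    momentum = 0.9, seed = 1) {
  stopifnot(is.matrix(x), all(hidden >= 1), max_iter >= 1)
  y01 <- as_binary01(y)
  n <- nrow(x)
  centre <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  z <- sweep(sweep(x, 2, centre), 2, scale, "/")

  sizes <- c(ncol(x), as.integer(hidden), 1L)
  L <- length(sizes) - 1
  W <- vector("list", L); b <- vector("list", L)
  with_stream(seed, "mlp_init", code = {
    for (l in seq_len(L)) {
      lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
      W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
                       sizes[l], sizes[l + 1])
      b[[l]] <- rep(0, sizes[l + 1])
    }
  })

  beta1 <- momentum; beta2 <- 0.999; eps <- 1e-8
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(v) v * 0); vb <- mb
  t_step <- 0
  for (epoch in seq_len(max_iter)) {
    # forward
    act <- vector("list", L + 1)
    act[[1]] <- z
    for (l in seq_len(L)) {
      pre <- sweep(act[[l]] %*% W[[l]], 2, b[[l]], "+")
      act[[l + 1]] <- if (l < L) pmax(pre, 0) else 1 / (1 + exp(-pre))
    }
    # backward: d(pre_L) for sigmoid + cross-entropy
    delta <- (act[[L + 1]] - y01) / n
    gW <- vector("list", L); gb <- vector("list", L)
    for (l in rev(seq_len(L))) {
      gW[[l]] <- crossprod(act[[l]], delta) + (alpha / n) * W[[l]]
      gb[[l]] <- colSums(delta)
      if (l > 1) {
        delta <- (delta %*% t(W[[l]])) * (act[[l]] > 0)
      }
    }
    # adam step
    t_step <- t_step + 1
    corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
    for (l in seq_len(L)) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
      W[[l]] <- W[[l]] - learning_rate_init *
        (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
      b[[l]] <- b[[l]] - learning_rate_init *
        (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
    }
  }
  structure(list(W = W, b = b, centre = centre, scale = scale,
                 sizes = sizes), class = "mlp_fit")
}

#' Predict positive-class probabilities from a fitted MLP
#'
#' @param fit an `mlp_fit`.
#' @param x samples x features matrix, columns in training order.
#' @return numeric vector of probabilities.
#' @export
mlp_predict <- function(fit, x) {
  stopifnot(inherits(fit, "mlp_fit"), is.matrix(x))
  z <- sweep(sweep(x, 2, fit$centre), 2, fit$scale, "/")
  L <- length(fit$W)
  for (l in seq_len(L)) {
    pre <- sweep(z %*% fit$W[[l]], 2, fit$b[[l]], "+")
    z <- if (l < L) pmax(pre, 0) else 1 / (1 + exp(-pre))
  }
  as.numeric(z)
}
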