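#' The four classifier families
#'
#' `rf` (random forest), `extra` (extremely randomized trees), `lgbm`
#' (leaf-wise gradient-boosted trees) and `mlp` (multilayer perceptron).
#' The vector order is also the tie-breaking precedence used when two
#' evaluations reach exactly the same AUC.
#'
#' @return character vector of algorithm ids in precedence order.
#' @export
algorithm_ids <- function() c("rf", "extra", "lgbm", "mlp")

check_algorithm <- function(algorithm) {
  match.arg(algorithm, algorithm_ids())
}

#' MLP hidden-layer architectures under the halving rule
#'
#' For each first-layer width `w` and depth `d` in `1..max_layers`, the
#' architecture is `(w, floor(w/2), floor(w/4), ...)` truncated to `d`
#' entries — each layer half the width of the previous one.
#'
#' @param first_layer_options first-layer widths (default `c(10,30,50,100)`).
#' @param max_layers maximum depth (default 3).
#' @return list of integer vectors (width tuples).
#' @export
mlp_architectures <- function(first_layer_options = c(10L, 30L, 50L, 100L),
                              max_layers = 3L) {
  stopifnot(all(first_layer_options >= 1), max_layers >= 1)
  out <- list()
  for (w in as.integer(first_layer_options)) {
    for (d in seq_len(max_layers)) {
      out[[length(out) + 1]] <- as.integer(floor(w / 2^(seq_len(d) - 1)))
    }
  }
  out
}

#' Default hyperparameter search space for an algorithm
#'
#' Parameter names follow the scikit-learn conventions of the original
#' cross-study framework: RF tunes `max_depth`, `max_features`,
#' `class_weight` and `bootstrap`; EXTRA the same minus `bootstrap`; LGBM
#' tunes `num_leaves`, `max_depth`, `n_estimators`, `reg_alpha` and
#' `learning_rate`; MLP tunes `max_iter`, `alpha`, `learning_rate_init`,
#' `momentum` and `hidden_layer_sizes` (12 architectures from
#' [mlp_architectures()]). Candidate values are package defaults spanning
#' standard ranges; every grid is overridable via `override`.
#'
#' @param algorithm one of [algorithm_ids()].
#' @param override named list replacing individual parameter definitions.
#' @return a `hyper_space`: list with `algorithm` and `parameters`, where
#'   each parameter is either `list(type = "choice", values = <list>)` or
#'   `list(type = "range", min =, max =, scale = "linear"|"log")`.
#' @export
default_space <- function(algorithm, override = NULL) {
  algorithm <- check_algorithm(algorithm)
  choice <- function(...) list(type = "choice", values = list(...))
  rng <- function(min, max, scale = "linear")
    list(type = "range", min = min, max = max, scale = scale)
  params <- switch(algorithm,
    rf = list(
      max_depth    = choice(2L, 4L, 8L, 16L, NA),   # NA = unlimited
      max_features = choice("sqrt", "log2", 0.5),
      class_weight = choice(NA, "balanced"),
      bootstrap    = choice(TRUE, FALSE)),
    extra = list(
      max_depth    = choice(2L, 4L, 8L, 16L, NA),
      max_features = choice("sqrt", "log2", 0.5),
      class_weight = choice(NA, "balanced")),
    lgbm = list(
      num_leaves    = choice(7L, 15L, 31L, 63L),
      max_depth     = choice(-1L, 4L, 8L),
      n_estimators  = choice(50L, 100L, 200L, 500L),
      reg_alpha     = rng(1e-3, 10, "log"),
      learning_rate = rng(1e-3, 0.3, "log")),
    mlp = list(
      hidden_layer_sizes = list(type = "choice",
                                values = mlp_architectures()),
      max_iter           = choice(200L, 500L, 1000L),
      alpha              = rng(1e-5, 1e-1, "log"),
      learning_rate_init = rng(1e-4, 1e-1, "log"),
      momentum           = choice(0.9, 0.95, 0.99)))
  if (!is.null(override)) {
    stopifnot(all(names(override) %in% names(params)))
    params[names(override)] <- override
  }
  structure(list(algorithm = algorithm, parameters = params),
            class = "hyper_space")
}

#' Sample hyperparameter candidates from a search space
#'
#' Randomized search: `n_iter` configurations drawn independently, each
#' parameter uniform over its candidate list or its (possibly
#' log-scaled) continuous range. Duplicates are permitted. Deterministic
#' given `seed`; draws are consumed in the fixed parameter order of the
#' space, so a configuration list is a pure function of (space, n_iter,
#' seed).
#'
#' @param space a `hyper_space` from [default_space()].
#' @param n_iter number of candidates (>= 1).
#' @param seed integer seed.
#' @return list of `candidate_config`s: lists with `algorithm` and
#'   `assignments` (and optionally a `route`, attached by the pipeline
#'   search).
#' @export
sample_candidates <- function(space, n_iter, seed = 1) {
  stopifnot(inherits(space, "hyper_space"), n_iter >= 1)
  if (length(space$parameters) == 0) stop("empty search space", call. = FALSE)
  with_stream(seed, "candidates", code = {
    lapply(seq_len(n_iter), function(i) {
      assignments <- lapply(space$parameters, function(p) {
        if (p$type == "choice") {
          p$values[[sample.int(length(p$values), 1)]]
        } else if (p$scale == "log") {
          exp(stats::runif(1, log(p$min), log(p$max)))
        } else {
          stats::runif(1, p$min, p$max)
        }
      })
      structure(list(algorithm = space$algorithm, assignments = assignments,
                     route = NULL),
                class = "candidate_config")
    })
  })
}

#' @export
format.candidate_config <- function(x, ...) {
  fmt1 <- function(v) {
    if (length(v) > 1) return(paste(v, collapse = "-"))
    if (is.numeric(v)) return(format(v, digits = 4))
    as.character(v)
  }
  paste0(x$algorithm,
         if (!is.null(x$route)) paste0("[", x$route, "]"), "(",
         paste(names(x$assignments),
               vapply(x$assignments, fmt1, ""), sep = "=", collapse = ", "),
         ")")
}

#' @export
print.candidate_config <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Fit one candidate configuration
#'
#' Trains the candidate's algorithm with its hyperparameter assignments on
#' a samples-x-features matrix. Training is deterministic given `seed` and
#' single-threaded. The returned model carries its training feature ids so
#' prediction can reindex new data onto them (see [predict_proba()]).
#'
#' @param config a `candidate_config` from [sample_candidates()].
#' @param x numeric training matrix (samples x features, named columns).
#' @param y training labels; both classes must be present.
#' @param seed integer seed.
#' @param num_trees forest size for rf/extra (default 100).
#' @return a `trained_model`.
#' @export
fit_candidate <- function(config, x, y, seed = 1,
                          num_trees = mc_defaults()$num_trees) {
  stopifnot(inherits(config, "candidate_config"), is.matrix(x))
  y <- as_delivery_mode(y)
  if (length(unique(y)) < 2)
    stop("training data contains a single class", call. = FALSE)
  a <- config$assignments
  fit <- switch(config$algorithm,
    rf    = fit_forest(x, y, a, seed, num_trees, extra = FALSE),
    extra = fit_forest(x, y, a, seed, num_trees, extra = TRUE),
    lgbm  = fit_gbm(x, y, a, seed),
    mlp   = mlp_fit(x, y,
                    hidden = a$hidden_layer_sizes, max_iter = a$max_iter,
                    alpha = a$alpha, learning_rate_init = a$learning_rate_init,
                    momentum = a$momentum, seed = seed),
    stop("unknown algorithm ", config$algorithm, call. = FALSE))
  structure(list(algorithm = config$algorithm, fit = fit,
                 feature_ids = colnames(x), config = config),
            class = "trained_model")
}

fit_forest <- function(x, y, a, seed, num_trees, extra) {
  p <- ncol(x)
  mtry <- switch(as.character(a$max_features),
                 sqrt = max(1L, floor(sqrt(p))),
                 log2 = max(1L, floor(log2(p))),
                 max(1L, floor(as.numeric(a$max_features) * p)))
  cw <- NULL
  if (!is.na(a$class_weight) && a$class_weight == "balanced") {
    tab <- table(y)
    cw <- as.numeric(length(y) / (length(tab) * tab))
    names(cw) <- names(tab)
  }
  bootstrap <- if (extra) FALSE else isTRUE(a$bootstrap)
  df <- data.frame(.y = y, x, check.names = FALSE)
  ranger::ranger(
    formula = .y ~ ., data = df,
    num.trees = num_trees, probability = TRUE,
    mtry = mtry,
    max.depth = if (is.na(a$max_depth)) 0 else a$max_depth,
    splitrule = if (extra) "extratrees" else "gini",
    num.random.splits = 1,
    replace = bootstrap,
    sample.fraction = 1,
    class.weights = cw,
    seed = seed, num.threads = 1, verbose = FALSE)
}

fit_gbm <- function(x, y, a, seed) {
  label <- as.integer(y == .mc_positive)
  dm <- xgboost::xgb.DMatrix(x, label = label, nthread = 1)
  params <- list(
    objective = "binary:logistic",
    tree_method = "hist",
    grow_policy = "lossguide",
    max_leaves = a$num_leaves,
    max_depth = if (a$max_depth < 0) 0L else a$max_depth,
    eta = a$learning_rate,
    alpha = a$reg_alpha,
    nthread = 1, seed = seed)
  xgboost::xgb.train(params = params, data = dm,
                     nrounds = a$n_estimators, verbose = 0)
}

#' Positive-class probabilities from a trained model or scoring function
#'
#' `model` may be a `trained_model` from [fit_candidate()] (new data are
#' reindexed onto the model's training features: unseen features dropped,
#' absent features zero-filled) or an arbitrary function
#' `matrix -> probabilities`, which lets ensembles and hand-built scorers
#' flow through the same importance machinery.
#'
#' @param model a `trained_model` or a function.
#' @param x samples x features numeric matrix with column names.
#' @return numeric vector of `P(caesarean)` per row of `x`.
#' @export
predict_proba <- function(model, x) {
  if (is.function(model)) return(model(x))
  stopifnot(inherits(model, "trained_model"), is.matrix(x))
  xm <- reindex_matrix(x, model$feature_ids)
  switch(model$algorithm,
    rf = ,
    extra = {
      pr <- stats::predict(model$fit, data = as.data.frame(xm),
                           num.threads = 1)$predictions
      unname(pr[, .mc_positive])
    },
    lgbm = {
      as.numeric(stats::predict(model$fit,
                                xgboost::xgb.DMatrix(xm, nthread = 1)))
    },
    mlp = mlp_predict(model$fit, xm))
}
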