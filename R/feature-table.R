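#' Preprocessing-route tag
#'
#' A feature table is tagged with the preprocessing route that produced it:
#' which taxonomy database the upstream pipeline used and which feature
#' space the table lives in. Routes are the categorical "pipeline
#' hyperparameter" that [pipeline_search()] tunes.
#'
#' @param database one of `"silva"`, `"greengenes"`, `"synthetic"`.
#' @param feature_space one of `"genera"`, `"pathways"`.
#' @return a `route_tag` object.
#' @export
route_tag <- function(database = "synthetic", feature_space = "genera") {
  database <- match.arg(database, c("silva", "greengenes", "synthetic"))
  feature_space <- match.arg(feature_space, c("genera", "pathways"))
  structure(list(database = database, feature_space = feature_space),
            class = "route_tag")
}

#' @export
format.route_tag <- function(x, ...) paste(x$database, x$feature_space, sep = ":")

#' @export
print.route_tag <- function(x, ...) { cat("<route>", format(x), "\n"); invisible(x) }

route_key <- function(route) format(route)

#' Samples-by-features abundance table
#'
#' The central container: a non-negative numeric matrix of samples (rows) by
#' features (columns), either raw counts or relative abundances, tagged with
#' its preprocessing route.
#'
#' @param values numeric matrix (samples x features), non-negative, finite.
#' @param sample_ids,feature_ids unique identifiers; default to dimnames.
#' @param mode `"counts"` or `"relative"`. In relative mode every row must
#'   sum to 1 within 1e-9.
#' @param route a [route_tag()].
#' @return a `feature_table` object.
#' @export
feature_table <- function(values, sample_ids = rownames(values),
                          feature_ids = colnames(values),
                          mode = c("relative", "counts"),
                          route = route_tag()) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids); feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values) || length(feature_ids) != ncol(values))
    stop("id lengths do not match matrix shape", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite abundance values", call. = FALSE)
  if (any(values < 0)) stop("negative abundance values", call. = FALSE)
  if (mode == "relative") {
    rs <- rowSums(values)
    if (any(rs == 0)) stop("all-zero row in relative-mode table", call. = FALSE)
    if (any(abs(rs - 1) > 1e-9))
      stop("relative-mode rows must sum to 1 (max deviation ",
           format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 feature_ids = feature_ids, mode = mode, route = route),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features, %s, route %s\n",
              length(x$sample_ids), length(x$feature_ids), x$mode,
              format(x$route)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Convert a count table to relative abundances
#'
#' Divides every row by its total so that rows sum to 1. Idempotent on
#' tables whose rows already sum to 1.
#'
#' @param table a [feature_table()].
#' @return a relative-mode `feature_table` with unchanged ids and route.
#' @export
normalize_relative <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  rs <- rowSums(table$values)
  if (any(rs == 0)) {
    stop("degenerate sample(s) with zero total abundance: ",
         paste(table$sample_ids[rs == 0], collapse = ", "), call. = FALSE)
  }
  feature_table(table$values / rs, table$sample_ids, table$feature_ids,
                mode = "relative", route = table$route)
}

#' Align feature tables onto the union of their feature sets
#'
#' Reindexes each table to the lexicographically sorted union of all
#' feature ids, filling features a table lacks with 0. Relative-mode rows
#' are not renormalized: only zeros are added, so row sums are unchanged.
#' This is the harmonization step that lets a model trained on one cohort
#' score samples from another whose observed taxa differ.
#'
#' @param tables a list of [feature_table()]s sharing a feature space.
#' @return a list of aligned `feature_table`s, in input order.
#' @export
align_features <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1,
            all(vapply(tables, inherits, TRUE, "feature_table")))
  spaces <- unique(vapply(tables, function(t) t$route$feature_space, ""))
  if (length(spaces) > 1)
    stop("tables mix feature spaces: ", paste(spaces, collapse = ", "),
         call. = FALSE)
  union_ids <- sort(unique(unlist(lapply(tables, `[[`, "feature_ids"))))
  if (length(union_ids) == 0) stop("empty feature union", call. = FALSE)
  lapply(tables, function(t) {
    m <- matrix(0, nrow(t$values), length(union_ids),
                dimnames = list(t$sample_ids, union_ids))
    m[, t$feature_ids] <- t$values
    feature_table(m, t$sample_ids, union_ids, mode = t$mode, route = t$route)
  })
}

#' Reindex a matrix onto a model's training feature set
#'
#' Features absent from `x` are zero-filled; extra features are dropped.
#' @param x samples x features numeric matrix with colnames.
#' @param feature_ids target feature ids, in training order.
#' @keywords internal
reindex_matrix <- function(x, feature_ids) {
  out <- matrix(0, nrow(x), length(feature_ids),
                dimnames = list(rownames(x), feature_ids))
  common <- intersect(colnames(x), feature_ids)
  out[, common] <- x[, common, drop = FALSE]
  out
}

#' One cohort's labels plus one feature table per preprocessing route
#'
#' @param cohort_id cohort identifier string.
#' @param age_stratum one of `"m1_2"`, `"m3_6"`, `"m9_12"` (sampling window
#'   in months after birth).
#' @param labels per-sample delivery mode, any dialect accepted by
#'   [as_delivery_mode()]. Both classes must be present with >= 2 samples
#'   for the dataset to be usable in model building.
#' @param tables a list of [feature_table()]s, all with identical
#'   `sample_ids` in identical order; names are derived from the routes.
#' @return a `cohort_dataset` object.
#' @export
cohort_dataset <- function(cohort_id, age_stratum = "m1_2", labels, tables) {
  age_stratum <- match.arg(age_stratum, c("m1_2", "m3_6", "m9_12"))
  labels <- as_delivery_mode(labels)
  stopifnot(is.list(tables), length(tables) >= 1)
  ids <- tables[[1]]$sample_ids
  for (t in tables) {
    stopifnot(inherits(t, "feature_table"))
    if (!identical(t$sample_ids, ids))
      stop("all route tables must share identical sample ids and order",
           call. = FALSE)
  }
  if (length(labels) != length(ids))
    stop("labels length does not match sample count", call. = FALSE)
  if (any(table(labels) < 2))
    stop("cohort '", cohort_id,
         "' needs >= 2 samples of each class for model building", call. = FALSE)
  names(tables) <- vapply(tables, function(t) route_key(t$route), "")
  if (anyDuplicated(names(tables))) stop("duplicate routes", call. = FALSE)
  structure(list(cohort_id = cohort_id, age_stratum = age_stratum,
                 labels = labels, tables = tables),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %s (%s): %d samples (%d caesarean / %d vaginal), routes: %s\n",
              x$cohort_id, x$age_stratum, length(x$labels),
              sum(x$labels == "caesarean"), sum(x$labels == "vaginal"),
              paste(names(x$tables), collapse = ", ")))
  invisible(x)
}

#' Routes available in a cohort dataset
#' @param dataset a [cohort_dataset()].
#' @return character vector of route keys (`"database:feature_space"`).
#' @export
routes_of <- function(dataset) names(dataset$tables)

#' Fetch one route's table from a cohort dataset
#' @param dataset a [cohort_dataset()].
#' @param route a [route_tag()] or route key string; `NULL` picks the only
#'   route (an error if several are attached).
#' @return a [feature_table()].
#' @export
get_route <- function(dataset, route = NULL) {
  if (is.null(route)) {
    if (length(dataset$tables) != 1)
      stop("dataset has several routes; pick one of: ",
           paste(names(dataset$tables), collapse = ", "), call. = FALSE)
    return(dataset$tables[[1]])
  }
  key <- if (inherits(route, "route_tag")) route_key(route) else route
  t <- dataset$tables[[key]]
  if (is.null(t))
    stop("route '", key, "' not present in cohort ", dataset$cohort_id,
         call. = FALSE)
  t
}

#' Attach an additional route table to a cohort dataset
#' @param dataset a [cohort_dataset()].
#' @param table a [feature_table()] over the same samples, same order.
#' @return the updated `cohort_dataset`.
#' @export
add_route <- function(dataset, table) {
  stopifnot(inherits(dataset, "cohort_dataset"), inherits(table, "feature_table"))
  if (!identical(table$sample_ids, dataset$tables[[1]]$sample_ids))
    stop("new route must cover identical samples in identical order",
         call. = FALSE)
  dataset$tables[[route_key(table$route)]] <- table
  dataset
}

#' Read a feature table with a trailing label column from TSV
#'
#' Expects UTF-8 tab-separated text with a header row of feature names, the
#' sample id in the first column and the class label in the last column.
#' Mode is inferred: relative if every row sums to 1 within 1e-6, counts
#' otherwise.
#'
#' @param path file path.
#' @param label_column name of the label column (default `"delivery_mode"`);
#'   it must be the last column.
#' @param route a [route_tag()] to attach.
#' @return a list with elements `table` (a [feature_table()]) and `labels`
#'   (a delivery-mode factor), row order preserved.
#' @export
read_feature_table <- function(path, label_column = "delivery_mode",
                               route = route_tag()) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("expected sample id, >=1 feature, label", call. = FALSE)
  if (names(df)[ncol(df)] != label_column)
    stop("last column is '", names(df)[ncol(df)], "', expected label column '",
         label_column, "'", call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample ids in ", path, call. = FALSE)
  labels <- as_delivery_mode(df[[ncol(df)]])
  vals <- as.matrix(df[, -c(1, ncol(df)), drop = FALSE])
  storage.mode(vals) <- "double"
  if (any(!is.finite(vals))) stop("non-numeric or non-finite values", call. = FALSE)
  if (any(vals < 0)) stop("negative abundance values", call. = FALSE)
  rownames(vals) <- ids
  mode <- if (all(abs(rowSums(vals) - 1) <= 1e-6)) "relative" else "counts"
  list(table = feature_table(vals, mode = mode, route = route), labels = labels)
}

#' Write a feature table (plus labels) in the TSV dialect of [read_feature_table()]
#'
#' Values are written with 17 significant digits so a read/write/read
#' round-trip reproduces them to 1e-12.
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @param labels optional delivery-mode labels (written as the last column).
#' @param label_column label column name.
#' @param id_column sample id column name.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, labels = NULL,
                                label_column = "delivery_mode",
                                id_column = "sample_id") {
  stopifnot(inherits(table, "feature_table"))
  vals <- table$values
  txt <- matrix(formatC(vals, digits = 17, format = "g"), nrow(vals),
                dimnames = dimnames(vals))
  df <- data.frame(id = table$sample_ids, txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  if (!is.null(labels)) {
    labels <- as_delivery_mode(labels)
    stopifnot(length(labels) == length(table$sample_ids))
    df[[label_column]] <- as.character(labels)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table from a BIOM file
#'
#' Thin wrapper around `biomformat::read_biom()` (supports the JSON 1.0 and
#' HDF5 2.1 dialects) returning the transposed (samples x features) counts
#' as a [feature_table()]. Requires the suggested package `biomformat`.
#'
#' @param path BIOM file path.
#' @param route a [route_tag()] to attach.
#' @return a counts-mode [feature_table()].
#' @export
read_biom_table <- function(path, route = route_tag()) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("read_biom_table() needs the 'biomformat' package", call. = FALSE)
  b <- biomformat::read_biom(path)
  m <- t(as.matrix(biomformat::biom_data(b)))  # biom is features x samples
  feature_table(m, mode = "counts", route = route)
}
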