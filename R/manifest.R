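#' Read a cohort manifest
#'
#' A manifest is a TSV with one row per (cohort, age stratum) and columns
#' `cohort_id, country, age_stratum, n_initial, n_available, n_caesarean,
#' n_vaginal, mean_age_months`. The packaged fixture
#' `system.file("extdata", "cohort_manifest.tsv", package = "microcross")`
#' encodes the twelve-cohort delivery-mode study design this package was
#' built around.
#'
#' @param path TSV path; defaults to the packaged manifest.
#' @return a `cohort_manifest` data frame.
#' @export
read_manifest <- function(path = system.file("extdata", "cohort_manifest.tsv",
                                             package = "microcross")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  needed <- c("cohort_id", "country", "age_stratum", "n_initial",
              "n_available", "n_caesarean", "n_vaginal", "mean_age_months")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Validate a cohort manifest and summarize per-stratum totals
#'
#' Checks the row invariants (integer counts >= 0;
#' `n_caesarean + n_vaginal == n_available`) and returns totals per age
#' stratum and overall.
#'
#' @param manifest a data frame as returned by [read_manifest()].
#' @return a data frame with one row per age stratum plus an `"all"` row,
#'   columns `age_stratum, n_cohorts, n_initial, n_available, n_caesarean,
#'   n_vaginal`.
#' @export
validate_manifest <- function(manifest) {
  counts <- c("n_initial", "n_available", "n_caesarean", "n_vaginal")
  for (col in counts) {
    v <- manifest[[col]]
    if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
      stop("manifest column ", col, " must hold non-negative integers",
           call. = FALSE)
  }
  bad <- manifest$n_caesarean + manifest$n_vaginal != manifest$n_available
  if (any(bad))
    stop("class counts do not sum to available samples for cohort(s): ",
         paste(manifest$cohort_id[bad], collapse = ", "), call. = FALSE)
  strata <- split(manifest, manifest$age_stratum)
  one <- function(name, rows) data.frame(
    age_stratum = name, n_cohorts = nrow(rows),
    n_initial = sum(rows$n_initial), n_available = sum(rows$n_available),
    n_caesarean = sum(rows$n_caesarean), n_vaginal = sum(rows$n_vaginal),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, c(
    lapply(names(strata), function(s) one(s, strata[[s]])),
    list(one("all", manifest))))
  rownames(out) <- NULL
  out
}
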