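test_that("feature_table enforces its invariants", {
  m <- matrix(c(0.25, 0.25, 0.5, 0.1, 0.2, 0.7), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("t1", "t2", "t3")))
  ft <- feature_table(m, mode = "relative")
  expect_identical(ft$sample_ids, c("a", "b"))
  expect_error(feature_table(m * -1, mode = "counts"), "negative")
  expect_error(feature_table(m * 2, mode = "relative"), "sum to 1")
  expect_error(feature_table(rbind(m, m), mode = "counts"), "duplicate sample")
  m0 <- m; m0[1, ] <- 0
  expect_error(feature_table(m0, mode = "relative"), "all-zero")
})

test_that("read_feature_table infers mode and validates the dialect", {
  tsv <- function(lines) {
    f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
    writeLines(lines, f); f
  }
  rel <- read_feature_table(tsv(c(
    "sample_id\tg1\tg2\tdelivery_mode",
    "s1\t0.25\t0.75\tcaesarean",
    "s2\t0.5\t0.5\tVaginal",
    "s3\t1\t0\tCS")))
  expect_equal(rel$table$mode, "relative")
  expect_equal(length(rel$table$sample_ids), 3)
  expect_equal(as.character(rel$labels), c("caesarean", "vaginal", "caesarean"))

  cnt <- read_feature_table(tsv(c(
    "sample_id\tg1\tg2\tdelivery_mode",
    "s1\t400\t600\t1", "s2\t1500\t500\t0")))
  expect_equal(cnt$table$mode, "counts")

  expect_error(read_feature_table(tsv(c(
    "sample_id\tg1\tg2\tdelivery_mode",
    "s1\t-0.25\t1.25\tcs", "s2\t0.5\t0.5\tvd"))), "negative")
  expect_error(read_feature_table(tsv(c(
    "sample_id\tg1\tg2\tdelivery_mode",
    "s1\t0.25\t0.75\tcs", "s1\t0.5\t0.5\tvd"))), "duplicate")
  expect_error(read_feature_table(tsv(c(
    "sample_id\tg1\tg2\tdelivery_mode",
    "s1\t0.25\t0.75\tbreech"))), "unknown class label")
})

test_that("write/read round-trip preserves values and order", {
  world <- small_world(n_cohorts = 1, n = 20, n_taxa = 8)
  ds <- world$cohorts[[1]]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ds$tables[[1]], f, labels = ds$labels)
  back <- read_feature_table(f)
  expect_identical(back$table$sample_ids, ds$tables[[1]]$sample_ids)
  expect_identical(back$table$feature_ids, ds$tables[[1]]$feature_ids)
  expect_lt(max(abs(back$table$values - ds$tables[[1]]$values)), 1e-12)
  expect_identical(back$labels, ds$labels)
  # write the re-read table again: byte-stable
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(back$table, f2, labels = back$labels)
  expect_identical(readLines(f), readLines(f2))
})

test_that("normalize_relative divides rows by their sums and is idempotent", {
  m <- matrix(c(2, 2, 4, 1, 0, 1), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("t1", "t2", "t3")))
  rel <- normalize_relative(feature_table(m, mode = "counts"))
  expect_equal(rel$values["a", ], c(t1 = 0.25, t2 = 0.25, t3 = 0.5))
  expect_equal(normalize_relative(rel)$values, rel$values)
  m[2, ] <- 0
  expect_error(normalize_relative(feature_table(m, mode = "counts")),
               "degenerate")
  # property: random count tables normalize to unit rows
  withr::with_seed(5, {
    for (i in 1:20) {
      x <- matrix(rpois(6 * 4, 7) + 1, 6, 4,
                  dimnames = list(paste0("s", 1:6), paste0("f", 1:4)))
      r <- normalize_relative(feature_table(x, mode = "counts"))
      expect_lt(max(abs(rowSums(r$values) - 1)), 1e-12)
    }
  })
})

test_that("align_features takes the sorted union, zero-fills, keeps sums", {
  t1 <- feature_table(matrix(c(0.4, 0.6), 1, dimnames = list("x", c("A", "B"))),
                      mode = "relative")
  t2 <- feature_table(matrix(c(0.3, 0.7), 1, dimnames = list("y", c("B", "C"))),
                      mode = "relative")
  al <- align_features(list(t1, t2))
  expect_identical(al[[1]]$feature_ids, c("A", "B", "C"))
  expect_equal(unname(al[[1]]$values[1, ]), c(0.4, 0.6, 0))
  expect_equal(sum(al[[2]]$values), 1)
  # identity on matching feature sets
  same <- align_features(list(t1, t1))
  expect_identical(same[[1]]$values, t1$values)
  # commutative in effect
  ba <- align_features(list(t2, t1))
  expect_identical(al[[1]]$values, ba[[2]]$values)
  expect_identical(al[[2]]$values, ba[[1]]$values)
})

test_that("manifest validation reproduces stratum totals and flags bad rows", {
  man <- read_manifest()
  s <- validate_manifest(man)
  row <- function(str) s[s$age_stratum == str, ]
  expect_equal(row("m1_2")$n_caesarean, 440)
  expect_equal(row("m1_2")$n_vaginal, 1017)
  expect_equal(row("all")$n_available, 3595)
  expect_equal(row("all")$n_initial, 4099)
  one <- data.frame(cohort_id = "X", country = "Y", age_stratum = "m1_2",
                    n_initial = 12, n_available = 10, n_caesarean = 5,
                    n_vaginal = 5, mean_age_months = 1)
  expect_equal(validate_manifest(one)$n_available, c(10, 10))
  bad <- one; bad$n_vaginal <- 4
  expect_error(validate_manifest(bad), "do not sum")
})

test_that("BIOM count tables round-trip through the optional reader", {
  skip_if_not_installed("biomformat")
  world <- small_world(n_cohorts = 1, n = 10, n_taxa = 6)
  cnt <- world$cohorts[[1]]$counts
  f <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(biomformat::make_biom(t(cnt$values)), f)
  back <- read_biom_table(f)
  expect_equal(back$values[cnt$sample_ids, cnt$feature_ids], cnt$values)
  expect_equal(back$mode, "counts")
})
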