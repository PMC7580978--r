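test_that("a single-record cohort survives a CSV round trip", {
  enc <- enc_of("r1", fever = TRUE, pct = 2.0,
                urine = urine_of(isolate("escherichia coli", 1e5)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(as_cohort(list(enc)), path)
  back <- read_cohort(path)
  expect_length(back, 1L)
  expect_equal(back[[1]]$urine_culture$isolates[[1]]$species, "escherichia coli")
  expect_equal(back[[1]]$urine_culture$isolates[[1]]$cfu_per_ml, 1e5)
  expect_equal(back[[1]]$pct_ng_ml, 2.0)
})

test_that("serialization round trip is the identity on the fixture cohort", {
  co <- fixture_cohort()
  strip <- function(x) {
    attributes(x) <- list(class = "tf_cohort")
    x
  }
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_cohort(co, path, fmt)
    back <- read_cohort(path, fmt)
    expect_equal(strip(back), strip(co), info = fmt)
  }
})

test_that("a missing mandatory column is a schema error naming the column", {
  enc <- enc_of("r1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(as_cohort(list(enc)), path)
  df <- utils::read.csv(path, colClasses = "character")
  df$pct_ng_ml <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_cohort(path), "pct_ng_ml")
})

test_that("an unknown species is a vocabulary error carrying the record id", {
  enc <- enc_of("weird1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(as_cohort(list(enc)), path)
  df <- utils::read.csv(path, colClasses = "character")
  df$urine_isolates <- "klingon bacillus:100000"
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_cohort(path), "klingon bacillus")
  expect_error(read_cohort(path), "weird1")
})

test_that("underage records are read but flagged against the inclusion criterion", {
  enc <- enc_of("kid", age = 17)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(as_cohort(list(enc)), path)
  expect_warning(back <- read_cohort(path), "18")
  expect_length(back, 1L)
  v <- validate_encounter(back[[1]])
  expect_length(v, 1L)
  expect_match(v, "18")
})

test_that("validate_encounter returns violations instead of raising", {
  expect_identical(validate_encounter(enc_of()), character())
  bad <- enc_of()
  bad$pct_ng_ml <- -1
  bad$sex <- "unknown"
  v <- validate_encounter(bad)
  expect_length(v, 2L)
  expect_true(any(grepl("pct_ng_ml", v)))
})

test_that("an empty cohort writes a header-only CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(as_cohort(list()), path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), 0L)
  expect_true("encounter_id" %in% names(df))
  expect_length(read_cohort(path), 0L)
})

test_that("every enumeration value in the fixture cohort round-trips", {
  co <- fixture_cohort()
  df <- as.data.frame(co)
  expect_equal(nrow(df), 403L)
  # MRSA flag survives the species token encoding
  expect_true(any(grepl("staphylococcus aureus\\*", df$urine_isolates)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  mrsa <- Filter(function(e) {
    any(vapply(e$urine_culture$isolates,
               function(i) isTRUE(i$methicillin_resistant), logical(1)))
  }, back)
  expect_length(mrsa, 1L)
})
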