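test_that("a complete row round-trips through read and write", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(one_row_cohort(), path)
  got <- read_cohort(path)
  expect_s3_class(got, "vms_cohort")
  expect_equal(nrow(got), 1L)
  expect_equal(got$b_dom2, 5)
  expect_equal(got$intervention, "cam")
})

test_that("write then read is the identity on generator output", {
  cohort <- generate_cohort(generator_config(n_couplets = 50, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  got <- read_cohort(path)
  expect_identical(got$couplet_id, cohort$couplet_id)
  expect_identical(got$likert, cohort$likert)
  expect_identical(got$intervention, cohort$intervention)
  expect_identical(got$menopause, cohort$menopause)
  for (col in c("b_dom1", "b_dom2", "b_dom3", "f_dom1", "f_dom2",
                "f_dom3", "age_years", "et_months", "adherence_days",
                "days_between", "vms_per_week")) {
    expect_equal(got[[col]], cohort[[col]], tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("validation rejects out-of-range and malformed input by name", {
  bad <- one_row_cohort()
  bad$b_dom1 <- 11
  expect_error(validate_cohort(bad), "b_dom1.*outside \\[0, 10\\]")

  bad2 <- one_row_cohort()
  bad2$intervention <- "acupuncture"
  expect_error(validate_cohort(bad2), "intervention.*unrecognised")

  bad3 <- one_row_cohort()
  bad3$days_between <- 0
  expect_error(validate_cohort(bad3), "days_between")

  headerless <- one_row_cohort()
  headerless$likert <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(headerless, path, row.names = FALSE)
  expect_error(read_cohort(path), "missing column.*likert")

  expect_error(read_cohort(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("missing values are written as empty cells and re-read as NA", {
  cohort <- one_row_cohort()
  cohort$f_dom2 <- NA_real_
  cohort$likert <- NA_character_
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  lines <- readLines(path)
  expect_length(lines, 2L)
  got <- read_cohort(path)
  expect_true(is.na(got$f_dom2))
  expect_true(is.na(got$likert))
})

test_that("an empty table writes a header-only file", {
  cohort <- generate_cohort(generator_config(n_couplets = 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  lines <- readLines(path)
  expect_length(lines, 1L)
  expect_identical(strsplit(lines, ",")[[1]], cohort_columns())
})

test_that("duplicate couplet ids are rejected", {
  two <- rbind(one_row_cohort(), one_row_cohort())
  expect_error(validate_cohort(two), "duplicated couplet_id")
})
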