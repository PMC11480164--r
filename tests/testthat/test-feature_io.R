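test_that("canonical panel has the fixed 6-class, 22-feature structure", {
  p <- canonical_panel()
  validate_panel(p)
  expect_named(p, c("FIRST", "GLCM", "GLDM", "GLSZM", "SHAPE", "GLRLM"))
  expect_equal(p$FIRST,
               c("10Percentile", "Mean", "Median", "Skewness", "Uniformity"))
  expect_length(panel_features(p), 22L)
  # GrayLevelNonUniformity sits in the run-length family here
  expect_true("GrayLevelNonUniformity" %in% p$GLRLM)
  expect_false("GrayLevelNonUniformity" %in% p$GLSZM)
})

test_that("feature-name normalization unifies prose and camel case", {
  expect_equal(normalize_feature_name("Joint entropy"),
               normalize_feature_name("JointEntropy"))
  expect_equal(normalize_feature_name("10 Percentile"), "10percentile")
})

test_that("wide CSV reading loads panel columns and ignores extras", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_tiny_wide_csv(f)
  fm <- read_feature_table(f)
  expect_equal(nrow(fm), 12L)  # 2 patients x 2 slices x 3 features
  expect_setequal(unique(fm$feature), c("Mean", "JointEntropy", "SurfaceArea"))

  write_tiny_wide_csv(f, extra_col = TRUE)
  expect_message(fm2 <- read_feature_table(f), "Energy")
  expect_false("Energy" %in% fm2$feature)
  expect_equal(nrow(fm2), 12L)
})

test_that("textual NA becomes a missing entry, not an error", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_tiny_wide_csv(f, na_cell = TRUE)
  fm <- read_feature_table(f)
  expect_equal(sum(is.na(fm$value)), 1L)
  # and it drives exclusion downstream
  flt <- filter_incomplete_patients(fm)
  expect_equal(flt$report$patient_id, "A")
  expect_match(flt$report$missing, "Mean")
})

test_that("malformed tables are format errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(patient_id = c("A", "A"), slice_index = c(1, 1),
                   Mean = c(1, 2))
  write.csv(df, f, row.names = FALSE)
  expect_error(read_feature_table(f), "duplicate")

  df2 <- data.frame(patient_id = "A", slice_index = 1, Mean = "abc")
  write.csv(df2, f, row.names = FALSE)
  expect_error(read_feature_table(f), "non-numeric")

  writeLines("x,y", f)
  expect_error(read_feature_table(f))
})

test_that("long (tidy) layout is auto-detected and round-trips", {
  fm <- tiny_cohort_fm(n_pat = 2L, n_slices = 2L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(fm, f)
  fm2 <- read_feature_table(f)
  expect_equal(as.data.frame(fm2), as.data.frame(fm))
})

test_that("exclusion filter reproduces the 80 -> 76 pathway", {
  fx <- study_fixture()
  flt <- filter_incomplete_patients(fx$features)
  expect_length(attr(flt$report, "retained_ids"), 76L)
  expect_setequal(flt$report$patient_id, c("H01", "CSV1", "CSV2", "CSV3"))
  expect_true(all(flt$report$missing == "Mean"))
})

test_that("filter is idempotent, conservative and order-invariant", {
  fx <- study_fixture()
  flt1 <- filter_incomplete_patients(fx$features)
  flt2 <- filter_incomplete_patients(flt1$matrix)
  expect_equal(as.data.frame(flt2$matrix), as.data.frame(flt1$matrix))
  expect_equal(nrow(flt2$report), 0L)

  n_in <- length(unique(fx$features$patient_id))
  expect_equal(nrow(flt1$report) + length(attr(flt1$report, "retained_ids")),
               n_in)

  shuffled <- fx$features[sample(nrow(fx$features))]
  flt3 <- filter_incomplete_patients(shuffled)
  expect_equal(as.data.frame(flt3$matrix), as.data.frame(flt1$matrix))
  expect_equal(flt3$report, flt1$report)
})

test_that("filter degenerate cases", {
  fm <- tiny_cohort_fm(n_pat = 2L)
  expect_equal(nrow(filter_incomplete_patients(fm)$report), 0L)

  # every patient missing a feature -> empty retained set, warning
  fm_all <- inject_missing(fm, c("P01", "P02"), "Mean")
  expect_warning(flt <- filter_incomplete_patients(fm_all), "all patients")
  expect_length(attr(flt$report, "retained_ids"), 0L)
  expect_setequal(flt$report$patient_id, c("P01", "P02"))
})

test_that("exclusion report serializes to JSON", {
  fx <- study_fixture()
  flt <- filter_incomplete_patients(fx$features)
  f <- withr::local_tempfile(fileext = ".json")
  write_exclusion_report(flt$report, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_setequal(back$patient_id, flt$report$patient_id)
})

test_that("label validation enforces the two-class contract", {
  expect_error(validate_labels(data.frame(patient_id = "A", status = "sick")),
               "healthy")
  expect_error(validate_labels(data.frame(patient_id = c("A", "A"),
                                          status = c("MAP", "MAP"))),
               "duplicate")
  expect_error(validate_labels(data.frame(patient_id = "A", status = "MAP",
                                          ctsi = 7)), "ctsi")
  ok <- validate_labels(data.frame(patient_id = "A", status = "MAP", ctsi = 3))
  expect_equal(ok$ctsi, 3L)
})
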