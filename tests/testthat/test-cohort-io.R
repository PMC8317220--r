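test_that("cohort CSV round-trip reproduces every field", {
  g <- generate_cohort(default_config(n = 50), seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(g$cohort, path)
  back <- read_cohort(path)
  expect_s3_class(back, "cohort_table")
  expect_equal(nrow(back), 50)
  for (col in names(g$cohort)) {
    expect_equal(back[[col]], g$cohort[[col]], label = col)
  }
  expect_identical(comorbidity_names(back), comorbidity_names(g$cohort))
})

test_that("delimiter auto-detection accepts tab-separated cohorts", {
  g <- generate_cohort(default_config(n = 10), seed = 8)
  csv <- withr::local_tempfile(fileext = ".csv")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(g$cohort, csv)
  writeLines(gsub(",", "\t", readLines(csv)), tsv)
  expect_equal(read_cohort(tsv)$glu_30, g$cohort$glu_30)
})

test_that("missing OGTT cells become missing entries, never zeros", {
  row <- make_patient_row("p1", "male", 975, 15000, 400)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(as_cohort(rbind(row, make_patient_row("p2", "female", 900, 12000, 330))),
               path)
  lines <- readLines(path)
  # blank the 30-min insulin cell of the first record
  header <- gsub('"', "", strsplit(lines[1], ",")[[1]])
  ins30 <- which(header == "ins_30")
  cells <- strsplit(lines[2], ",")[[1]]
  cells[ins30] <- ""
  lines[2] <- paste(cells, collapse = ",")
  writeLines(lines, path)
  back <- read_cohort(path)
  expect_true(is.na(back$ins_30[1]))
  expect_false(is.na(back$ins_30[2]))
  expect_false(any(back$ins_30 == 0, na.rm = TRUE))
})

test_that("validation is total: malformed inputs yield diagnostics, not coercion", {
  base <- rbind(make_patient_row("a", "male", 975, 15000, 400),
                make_patient_row("b", "female", 900, 12000, 330))
  neg <- base; neg$uric_acid[2] <- -5
  err <- expect_error(as_cohort(neg), class = "obty_error_validation")
  expect_match(conditionMessage(err), "uric_acid")
  expect_match(conditionMessage(err), "2") # names the offending row

  dup <- base; dup$patient_id <- c("a", "a")
  expect_error(as_cohort(dup), class = "obty_error_integrity")

  nosex <- base; nosex$sex <- NULL
  expect_error(as_cohort(nosex), class = "obty_error_schema")

  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(as_cohort(base), path)
  txt <- readLines(path)
  txt[2] <- sub("400", "4o0", txt[2])
  writeLines(txt, path)
  expect_error(read_cohort(path), class = "obty_error_validation")
})

test_that("empty cohort writes a header-only file that reads back empty", {
  g <- generate_cohort(default_config(n = 20), seed = 9)
  empty <- g$cohort[0, ]
  empty <- as_cohort(as.data.frame(empty), comorbidities = comorbidity_names(g$cohort))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(empty, path)
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_cohort(path)), 0L)
})

test_that("unknown comorbidity states survive the round trip as sentinel tokens", {
  row <- make_patient_row("p1", "male", 975, 15000, 400)
  row$diabetes <- "unknown"
  co <- as_cohort(row, comorbidities = "diabetes")
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_match(paste(readLines(path), collapse = ""), "unknown")
  back <- read_cohort(path)
  expect_identical(as.character(back$diabetes), "unknown")
  # 1/0 tokens are accepted on read too
  txt <- readLines(path)
  txt[2] <- sub('"unknown"$', "1", txt[2])
  writeLines(txt, path)
  expect_identical(as.character(read_cohort(path)$diabetes), "present")
})

test_that("model JSON round-trips losslessly and re-serializes bit-identically", {
  g <- generate_cohort(default_config(n = 120), seed = 10)
  fit <- fit_sex_stratified(g$cohort, "kmeans",
                            config = clustering_config(k_range = 4), seed = 1)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_model(fit, p1)
  m2 <- read_model(p1)
  write_model(m2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(m2$strata$male$centers, fit$strata$male$centers)
  expect_equal(m2$strata$female$normalization$sd, fit$strata$female$normalization$sd)
  expect_identical(m2$strata$male$labels, fit$strata$male$labels)
})

test_that("model reader rejects truncated, version-mismatched and one-stratum files", {
  m <- make_reference_model(seed = 11)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)

  txt <- readLines(path)
  trunc <- withr::local_tempfile(fileext = ".json")
  writeLines(head(txt, length(txt) %/% 2), trunc)
  expect_error(read_model(trunc), class = "obty_error_parse")

  doc <- jsonlite::read_json(path)
  bad <- withr::local_tempfile(fileext = ".json")
  doc$format_version <- "99.0"
  jsonlite::write_json(doc, bad, auto_unbox = TRUE, digits = NA)
  expect_error(read_model(bad), class = "obty_error_incompat")

  doc <- jsonlite::read_json(path)
  doc$strata$female <- NULL
  jsonlite::write_json(doc, bad, auto_unbox = TRUE, digits = NA)
  expect_error(read_model(bad), class = "obty_error_validation")
})
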