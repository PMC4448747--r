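write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

header <- paste(activity_columns(), collapse = "\t")

row_line <- function(compound = "C1", target = "T1", assay = "A1",
                     score = "9", year = "2000", value = "10",
                     relation = "=", comment = "") {
  paste(compound, target, "SINGLE PROTEIN", "Homo sapiens", assay, "D",
        score, "Ki", relation, comment, year, value, sep = "\t")
}

test_that("a well-formed table loads with nothing rejected", {
  path <- write_tsv_fixture(c(header,
                              row_line("C1", "T1", "A1"),
                              row_line("C2", "T2", "A2"),
                              row_line("C3", "T3", "A3")))
  rec <- read_activity_table(path)
  rep <- validation_report(rec)
  expect_equal(nrow(rec), 3)
  expect_equal(rep$n_rejected, 0)
  expect_equal(rep$n_records_read, 3)
  expect_type(rec$confidence_score, "integer")
  expect_type(rec$release_year, "integer")
  expect_type(rec$measurement_value, "double")
})

test_that("rows failing validation are counted under a named reason, never dropped silently", {
  path <- write_tsv_fixture(c(
    header,
    row_line("C1", "T1", "A1"),
    row_line("C2", "T2", "A2", score = "x"),
    row_line("C3", "T3", "A3", score = "11"),
    row_line("", "T4", "A4"),
    row_line("C5", "T5", "A5", year = "July 1999"),
    row_line("C6", "T6", "A6", year = "1492"),
    row_line("C7", "T7", "A7", value = "-3"),
    row_line("C8", "T8", "A8")
  ))
  rec <- read_activity_table(path)
  rep <- validation_report(rec)
  expect_equal(nrow(rec), 2)
  expect_equal(rep$n_rejected, 6)
  expect_equal(rep$n_records_read, rep$n_retained + rep$n_rejected)
  expect_equal(rep$rejection_reasons[["bad_confidence_score"]], 2)
  expect_equal(rep$rejection_reasons[["missing_compound_id"]], 1)
  expect_equal(rep$rejection_reasons[["bad_release_year"]], 1)
  expect_equal(rep$rejection_reasons[["release_year_out_of_range"]], 1)
  expect_equal(rep$rejection_reasons[["bad_measurement_value"]], 1)
  expect_equal(sum(rep$rejection_reasons), rep$n_rejected)
})

test_that("byte-identical rows are deduplicated and counted", {
  path <- write_tsv_fixture(c(header, row_line(), row_line()))
  rec <- read_activity_table(path)
  rep <- validation_report(rec)
  expect_equal(nrow(rec), 1)
  expect_equal(rep$n_duplicates, 1)
  expect_equal(rep$rejection_reasons[["duplicate_record"]], 1)
  expect_equal(rep$n_records_read, rep$n_retained + rep$n_rejected)
})

test_that("full dates are truncated to the calendar year", {
  path <- write_tsv_fixture(c(header,
                              row_line("C1", year = "1999-07-15"),
                              row_line("C2", year = "2003/1/2"),
                              row_line("C3", year = "2010")))
  rec <- read_activity_table(path)
  expect_equal(rec$release_year, c(1999L, 2003L, 2010L))
  expect_equal(validation_report(rec)$n_rejected, 0)
})

test_that("missing release years are retained but counted", {
  path <- write_tsv_fixture(c(header,
                              row_line("C1", year = ""),
                              row_line("C2", year = "2001")))
  rec <- read_activity_table(path)
  expect_equal(nrow(rec), 2)
  expect_true(is.na(rec$release_year[rec$compound_id == "C1"]))
  expect_equal(validation_report(rec)$n_missing_release_year, 1)
})

test_that("schema and I/O failures are explicit errors", {
  expect_error(read_activity_table(tempfile("nope")), class = "promtime_io_error")
  no_col <- write_tsv_fixture(c("compound_id\ttarget_id", "C1\tT1"))
  expect_error(read_activity_table(no_col), class = "promtime_schema_error")
  expect_error(read_activity_table(no_col), "assay_id")
  empty <- write_tsv_fixture(character())
  expect_error(read_activity_table(empty), class = "promtime_schema_error")
})

test_that("column mapping lets renamed exports load through the same reader", {
  path <- withr::local_tempfile(fileext = ".tsv")
  lines <- c(sub("compound_id", "molecule_chembl_id", header),
             row_line("CHEMBL25", "T1", "A1"))
  writeLines(lines, path)
  rec <- read_activity_table(path, col_map = c(compound_id = "molecule_chembl_id"))
  expect_equal(rec$compound_id, "CHEMBL25")
})

test_that("write then read is the identity on valid record tables", {
  set.seed(11)
  sim <- generate_activity_data(generator_config(n_compounds = 40, seed = 11))
  rec <- sim$records
  rec$release_year[1] <- NA_integer_  # missing year survives the round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_activity_table(rec, path)
  back <- read_activity_table(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(rec), ignore_attr = TRUE)
  expect_equal(validation_report(back)$n_rejected, 0)
})

test_that("an empty table writes a header-only file", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_activity_table(worked_example_fixture()[0, ], path)
  expect_equal(readLines(path), header)
})

test_that("exclude_missing_release_year keeps exactly the dated records and is idempotent", {
  rec <- make_records(sprintf("C%d", 1:10), "T1", 2000,
                      release_year = c(rep(2000L, 7), rep(NA_integer_, 3)))
  kept <- exclude_missing_release_year(rec)
  expect_equal(nrow(kept), 7)
  expect_equal(exclude_missing_release_year(kept), kept)
  all_dated <- make_records("C1", "T1", 1999)
  expect_equal(exclude_missing_release_year(all_dated), all_dated)
  none_dated <- make_records("C1", "T1", 1999, release_year = NA_integer_)
  expect_equal(nrow(exclude_missing_release_year(none_dated)), 0)
})

test_that("as_activity_table enforces the record invariants", {
  good <- make_records("C1", "T1", 2000)
  expect_equal(as_activity_table(as.data.frame(good)), good)
  expect_error(as_activity_table(dplyr::mutate(good, compound_id = "")), "compound_id")
  expect_error(as_activity_table(dplyr::mutate(good, confidence_score = 12L)), "confidence_score")
  expect_error(as_activity_table(dplyr::mutate(good, measurement_value = -1)), "measurement_value")
  expect_error(as_activity_table(good[, 1:3]), class = "promtime_schema_error")
})
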