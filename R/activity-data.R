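#' Canonical activity-record columns
#'
#' Column names of the canonical activity-record table: one row per
#' compound-target-assay measurement, as exported from a ChEMBL-like
#' bioactivity database. Empty strings in delimited files are read as
#' missing values.
#'
#' @return Character vector of the twelve canonical column names.
#' @export
#' @examples
#' activity_columns()
activity_columns <- function() {
  c(
    "compound_id", "target_id", "target_type", "organism", "assay_id",
    "relationship_type", "confidence_score", "measurement_type",
    "measurement_relation", "activity_comment", "release_year",
    "measurement_value"
  )
}

# columns that must be non-empty on every record
id_columns <- function() c("compound_id", "target_id", "assay_id")

assert_activity_cols <- function(x, cols = activity_columns(),
                                 arg = deparse(substitute(x))) {
  if (!is.data.frame(x)) {
    rlang::abort(sprintf("`%s` must be a data frame of activity records.", arg))
  }
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    rlang::abort(
      sprintf(
        "`%s` is missing required column(s): %s.",
        arg, paste(missing, collapse = ", ")
      ),
      class = "promtime_schema_error"
    )
  }
  invisible(x)
}

#' Validate and coerce a data frame of activity records
#'
#' Checks that all canonical columns are present, coerces them to their
#' canonical types (`confidence_score` and `release_year` to integer,
#' `measurement_value` to double, the rest to character) and enforces the
#' record invariants: non-empty compound/target/assay identifiers,
#' confidence scores in 0-9 when present, and non-negative measurement
#' values. Invariant violations are errors; use [read_activity_table()]
#' when rows of unknown quality must be screened and counted instead.
#'
#' @param x A data frame carrying the columns of [activity_columns()].
#' @return A tibble with canonical column order and types.
#' @export
as_activity_table <- function(x) {
  assert_activity_cols(x)
  out <- tibble::as_tibble(x)[activity_columns()]
  chr_cols <- setdiff(activity_columns(),
                      c("confidence_score", "release_year", "measurement_value"))
  out <- dplyr::mutate(
    out,
    dplyr::across(dplyr::all_of(chr_cols), as.character),
    confidence_score = as.integer(.data$confidence_score),
    release_year = as.integer(.data$release_year),
    measurement_value = as.double(.data$measurement_value)
  )
  for (col in id_columns()) {
    bad <- is.na(out[[col]]) | trimws(out[[col]]) == ""
    if (any(bad)) {
      rlang::abort(sprintf("%d record(s) have an empty `%s`.", sum(bad), col))
    }
  }
  cs <- out$confidence_score
  if (any(!is.na(cs) & (cs < 0L | cs > 9L))) {
    rlang::abort("`confidence_score` must be in [0, 9] when present.")
  }
  mv <- out$measurement_value
  if (any(!is.na(mv) & mv < 0)) {
    rlang::abort("`measurement_value` must be non-negative when present.")
  }
  out
}

# Parse free-form release dates to calendar years. Accepts a bare 4-digit
# year or a date string beginning with one ("1999-07-01", "1999/7/1");
# anything else is unparseable (NA with ok = FALSE). Empty input is a
# legitimate missing value (NA with ok = TRUE).
parse_release_year <- function(x) {
  x <- trimws(as.character(x))
  empty <- is.na(x) | x == ""
  m <- regmatches(x, regexec("^([0-9]{4})([-/. ].*)?$", x))
  year <- vapply(m, function(g) {
    if (length(g) == 0) NA_integer_ else as.integer(g[[2]])
  }, integer(1))
  list(year = ifelse(empty, NA_integer_, year),
       ok = empty | !is.na(year))
}

new_validation_report <- function(n_read, n_retained, n_rejected, n_duplicates,
                                  n_missing_release_year, reasons) {
  structure(
    list(
      n_records_read = n_read,
      n_retained = n_retained,
      n_rejected = n_rejected,
      n_duplicates = n_duplicates,
      n_missing_release_year = n_missing_release_year,
      rejection_reasons = reasons
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %d row(s) read: %d retained, %d rejected\n",
    x$n_records_read, x$n_retained, x$n_rejected
  ))
  if (length(x$rejection_reasons) > 0) {
    for (r in names(x$rejection_reasons)) {
      cat(sprintf("  - %s: %d\n", r, x$rejection_reasons[[r]]))
    }
  }
  cat(sprintf("  retained rows with missing release_year: %d\n",
              x$n_missing_release_year))
  invisible(x)
}

#' Retrieve the validation report attached to a read activity table
#'
#' @param x A tibble returned by [read_activity_table()].
#' @return A `validation_report` object: row counts read / retained /
#'   rejected, duplicate count, count of retained rows with missing
#'   `release_year`, and a named vector of per-reason rejection counts.
#' @seealso [read_activity_table()]
#' @export
validation_report <- function(x) {
  rep <- attr(x, "validation_report", exact = TRUE)
  if (is.null(rep)) {
    rlang::abort("`x` carries no validation report; was it produced by read_activity_table()?")
  }
  rep
}

#' Read a delimited table of bioactivity records
#'
#' Reads one compound-target-assay measurement per row from a delimited
#' UTF-8 text file with a header row, validates every row, and returns the
#' parseable rows as a typed tibble with a [validation_report()] attached.
#' Rows are never dropped silently: each rejected row is tallied under a
#' named reason, and byte-identical duplicate rows are removed and counted.
#' Release dates may be full dates; they are truncated to the calendar
#' year, the resolution at which all downstream time-course statistics
#' operate.
#'
#' Rejection reasons are, in order of precedence per row:
#' `missing_compound_id`, `missing_target_id`, `missing_assay_id`,
#' `bad_confidence_score` (unparseable or outside 0-9),
#' `bad_release_year` (present but not year-resolvable),
#' `release_year_out_of_range`, `bad_measurement_value` (unparseable or
#' negative), and `duplicate_record`.
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter; tab by default, `","` for CSV exports.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(compound_id = "molecule_chembl_id")`, so real database exports and
#'   synthetic tables load through the same reader.
#' @param year_range Plausible release-year range; years outside it are
#'   rejected. Defaults to 1900 through the current year.
#' @return A tibble of validated activity records (columns of
#'   [activity_columns()]), with the validation report in attribute
#'   `"validation_report"`.
#' @export
#' @examples
#' path <- tempfile(fileext = ".tsv")
#' write_activity_table(worked_example_fixture(), path)
#' rec <- read_activity_table(path)
#' validation_report(rec)
read_activity_table <- function(path, delim = "\t", col_map = NULL,
                                year_range = c(1900L, as.integer(format(Sys.Date(), "%Y")))) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path), class = "promtime_io_error")
  }
  raw <- readr::read_delim(
    path, delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  if (ncol(raw) == 0 || length(readr::read_lines(path, n_max = 1, progress = FALSE)) == 0) {
    rlang::abort(sprintf("File has no header row: %s", path),
                 class = "promtime_schema_error")
  }
  if (!is.null(col_map)) {
    for (canonical in names(col_map)) {
      src <- col_map[[canonical]]
      if (!src %in% names(raw)) {
        rlang::abort(sprintf("Mapped column `%s` (for `%s`) not in file.", src, canonical),
                     class = "promtime_schema_error")
      }
      names(raw)[names(raw) == src] <- canonical
    }
  }
  assert_activity_cols(raw, arg = path)
  raw <- raw[activity_columns()]
  n_read <- nrow(raw)

  # Per-row screening: first failing check (in documented precedence order)
  # becomes the row's rejection reason.
  reason <- rep(NA_character_, n_read)
  flag <- function(bad, why) reason <<- ifelse(is.na(reason) & bad, why, reason)

  for (col in id_columns()) {
    flag(is.na(raw[[col]]) | trimws(raw[[col]]) == "", paste0("missing_", col))
  }

  cs_raw <- trimws(raw$confidence_score)
  cs_empty <- is.na(cs_raw) | cs_raw == ""
  cs <- suppressWarnings(as.integer(cs_raw))
  flag(!cs_empty & (is.na(cs) | cs != suppressWarnings(as.numeric(cs_raw)) |
                      cs < 0L | cs > 9L),
       "bad_confidence_score")

  ry <- parse_release_year(raw$release_year)
  flag(!ry$ok, "bad_release_year")
  flag(ry$ok & !is.na(ry$year) &
         (ry$year < year_range[[1]] | ry$year > year_range[[2]]),
       "release_year_out_of_range")

  mv_raw <- trimws(raw$measurement_value)
  mv_empty <- is.na(mv_raw) | mv_raw == ""
  mv <- suppressWarnings(as.double(mv_raw))
  flag(!mv_empty & (is.na(mv) | mv < 0), "bad_measurement_value")

  rec <- tibble::tibble(
    compound_id = as.character(raw$compound_id),
    target_id = as.character(raw$target_id),
    target_type = as.character(raw$target_type),
    organism = as.character(raw$organism),
    assay_id = as.character(raw$assay_id),
    relationship_type = as.character(raw$relationship_type),
    confidence_score = ifelse(cs_empty, NA_integer_, cs),
    measurement_type = as.character(raw$measurement_type),
    measurement_relation = as.character(raw$measurement_relation),
    activity_comment = as.character(raw$activity_comment),
    release_year = ry$year,
    measurement_value = ifelse(mv_empty, NA_real_, mv)
  )

  keep <- is.na(reason)
  rec <- rec[keep, ]
  dup <- duplicated(rec)
  n_dup <- sum(dup)
  rec <- rec[!dup, ]

  reasons <- table(reason[!keep])
  reasons <- stats::setNames(as.integer(reasons), names(reasons))
  if (n_dup > 0) reasons[["duplicate_record"]] <- n_dup

  report <- new_validation_report(
    n_read = n_read,
    n_retained = nrow(rec),
    n_rejected = n_read - nrow(rec),
    n_duplicates = n_dup,
    n_missing_release_year = sum(is.na(rec$release_year)),
    reasons = reasons
  )
  attr(rec, "validation_report") <- report
  rec
}

#' Write activity records to a delimited file
#'
#' Serializes a canonical activity-record tibble as UTF-8 delimited text
#' with a header row; missing values become empty strings. Reading the
#' file back with [read_activity_table()] reproduces the records
#' field-for-field (doubles are written with round-trip-exact precision).
#'
#' @param x A data frame of activity records (canonical columns).
#' @param path Output file path.
#' @param delim Field delimiter; tab by default.
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(x, path, delim = "\t") {
  assert_activity_cols(x)
  readr::write_delim(
    tibble::as_tibble(x)[activity_columns()],
    path, delim = delim, na = "", progress = FALSE
  )
  invisible(path)
}

#' Drop records without a release year
#'
#' Time-course analyses require a release date on every record; this keeps
#' exactly the records whose `release_year` is present. Idempotent; the
#' input is not modified.
#'
#' @param x A data frame of activity records.
#' @return A tibble of the records with a known release year.
#' @export
exclude_missing_release_year <- function(x) {
  assert_activity_cols(x, cols = "release_year")
  out <- dplyr::filter(tibble::as_tibble(x), !is.na(.data$release_year))
  attr(out, "validation_report") <- NULL
  out
}
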