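entity_kinds <- function() c("compounds", "targets", "assays", "activities")

require_complete_years <- function(x, op) {
  if (any(is.na(x$release_year))) {
    rlang::abort(sprintf(
      "%s() requires a release_year on every record; run exclude_missing_release_year() first.",
      op
    ))
  }
}

new_growth_table <- function(rows, entity) {
  structure(rows, entity = entity, class = c("growth_tbl", class(tibble::tibble())))
}

#' Annual growth table for one entity kind
#'
#' Tabulates, for every year between the first and last release year in
#' the data, how many entities became newly available (`n_new`) and how
#' many were available in total (`n_cumulative`). For compounds, targets
#' and assays an entity counts as new in the year of its earliest record,
#' once over the whole table; for activities every record counts in its
#' own release year. Years with no new entries appear with `n_new = 0`.
#'
#' @param x A data frame of activity records, all with a release year.
#' @param entity One of `"compounds"`, `"targets"`, `"assays"`,
#'   `"activities"`.
#' @return A `growth_tbl` tibble with columns `year`, `n_new`,
#'   `n_cumulative`; the entity kind is kept in attribute `"entity"`.
#' @export
#' @examples
#' growth_table(worked_example_fixture(), "activities")
growth_table <- function(x, entity = entity_kinds()) {
  entity <- match.arg(entity)
  assert_activity_cols(x, cols = c("compound_id", "target_id", "assay_id", "release_year"))
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) {
    return(new_growth_table(
      tibble::tibble(year = integer(), n_new = integer(), n_cumulative = integer()),
      entity
    ))
  }
  require_complete_years(x, "growth_table")
  debut_years <- switch(
    entity,
    activities = x$release_year,
    compounds = first_seen(x, "compound_id")$year,
    targets = first_seen(x, "target_id")$year,
    assays = first_seen(x, "assay_id")$year
  )
  rows <- tibble::tibble(year = debut_years) |>
    dplyr::count(.data$year, name = "n_new") |>
    tidyr::complete(
      year = seq(min(x$release_year), max(x$release_year)),
      fill = list(n_new = 0L)
    ) |>
    dplyr::arrange(.data$year) |>
    dplyr::mutate(n_cumulative = cumsum(.data$n_new))
  new_growth_table(rows, entity)
}

# earliest release year per entity id
first_seen <- function(x, id_col) {
  x |>
    dplyr::group_by(id = .data[[id_col]]) |>
    dplyr::summarise(year = min(.data$release_year), .groups = "drop")
}

#' Assemble a growth table from precomputed counts
#'
#' Builds a `growth_tbl` from per-year counts already in hand - e.g. the
#' published summary counts of a database release - so that growth
#' arithmetic such as [fold_increase()] can be applied to them. Supply
#' `n_new` (cumulative totals are derived by summation over a complete
#' year sequence) or `n_cumulative` directly, or both.
#'
#' @param df A data frame with column `year` and `n_new` and/or
#'   `n_cumulative`.
#' @param entity Entity kind label (see [growth_table()]).
#' @return A `growth_tbl` tibble.
#' @export
#' @examples
#' as_growth_table(
#'   data.frame(year = c(1976, 1977), n_new = c(3188, 6496)),
#'   "compounds"
#' )
as_growth_table <- function(df, entity = entity_kinds()) {
  entity <- match.arg(entity)
  if (!"year" %in% names(df)) rlang::abort("`df` must have a `year` column.")
  has_new <- "n_new" %in% names(df)
  has_cum <- "n_cumulative" %in% names(df)
  if (!has_new && !has_cum) {
    rlang::abort("`df` must have `n_new` and/or `n_cumulative`.")
  }
  rows <- tibble::as_tibble(df) |>
    dplyr::arrange(.data$year) |>
    dplyr::mutate(year = as.integer(.data$year))
  if (anyDuplicated(rows$year)) rlang::abort("`year` values must be unique.")
  if (!has_cum) {
    if (!identical(rows$year, seq(min(rows$year), max(rows$year)))) {
      rlang::abort("Deriving `n_cumulative` from `n_new` needs a gap-free year sequence.")
    }
    rows$n_cumulative <- cumsum(rows$n_new)
  }
  if (!has_new) rows$n_new <- NA_integer_
  if (is.unsorted(rows$n_cumulative)) {
    rlang::abort("`n_cumulative` must be non-decreasing in year.")
  }
  new_growth_table(rows[c("year", "n_new", "n_cumulative")], entity)
}

#' Fold increase in cumulative counts between two years
#'
#' Ratio of the cumulative entity count at `year_to` to that at
#' `year_from`. Returned at full precision; round to one decimal when
#' reporting, as growth factors are conventionally printed.
#'
#' @param table A `growth_tbl` (or any data frame with `year` and
#'   `n_cumulative`).
#' @param year_from,year_to Years present in the table.
#' @return A single number, `n_cumulative(year_to) / n_cumulative(year_from)`.
#' @export
#' @examples
#' g <- as_growth_table(
#'   data.frame(year = c(1976, 1977), n_new = c(3188, 6496)), "compounds"
#' )
#' fold_increase(g, 1976, 1977)
fold_increase <- function(table, year_from, year_to) {
  if (!all(c("year", "n_cumulative") %in% names(table))) {
    rlang::abort("`table` must have `year` and `n_cumulative` columns.")
  }
  cum_at <- function(y) {
    i <- which(table$year == y)
    if (length(i) != 1) {
      rlang::abort(sprintf("Year %s is not present in the growth table.", y))
    }
    table$n_cumulative[[i]]
  }
  from <- cum_at(year_from)
  if (from <= 0) {
    rlang::abort(sprintf("Cumulative count at %s is zero; fold increase undefined.", year_from))
  }
  cum_at(year_to) / from
}

#' Per-compound cumulative promiscuity time course
#'
#' For every compound, computes its promiscuity degree in each year from
#' its first recorded year to the horizon: the number of distinct targets
#' over all of its records released up to and including that year. A
#' target contributes from its earliest year onward; later re-measurements
#' of the same target neither add nor reset anything, so the degree is
#' non-decreasing. Records dated after the horizon are ignored.
#'
#' @param x A data frame of activity records, all with a release year.
#' @param horizon Last year of the time course; defaults to the latest
#'   release year in the data.
#' @return A `promiscuity_series` tibble in long form - one row per
#'   compound and year (`compound_id`, `year`, `degree`), covering each
#'   compound from its first year through the horizon - with the horizon
#'   in attribute `"horizon"`.
#' @export
#' @examples
#' promiscuity_series(worked_example_fixture())
promiscuity_series <- function(x, horizon = NULL) {
  assert_activity_cols(x, cols = c("compound_id", "target_id", "release_year"))
  x <- tibble::as_tibble(x)
  if (nrow(x) > 0) require_complete_years(x, "promiscuity_series")
  if (is.null(horizon)) {
    horizon <- if (nrow(x) == 0) NA_integer_ else max(x$release_year)
  }
  horizon <- as.integer(horizon)
  x <- dplyr::filter(x, .data$release_year <= horizon)
  if (nrow(x) == 0) {
    return(structure(
      tibble::tibble(compound_id = character(), year = integer(), degree = integer()),
      horizon = horizon,
      class = c("promiscuity_series", class(tibble::tibble()))
    ))
  }
  # year in which each target first appears for each compound
  first_hit <- x |>
    dplyr::group_by(.data$compound_id, .data$target_id) |>
    dplyr::summarise(year = min(.data$release_year), .groups = "drop")
  gains <- first_hit |>
    dplyr::count(.data$compound_id, .data$year, name = "n_gained")
  debut <- gains |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(first_year = min(.data$year), .groups = "drop")
  span <- horizon - debut$first_year + 1L
  grid <- tibble::tibble(
    compound_id = rep(debut$compound_id, span),
    year = as.integer(sequence(span, from = debut$first_year))
  )
  out <- grid |>
    dplyr::left_join(gains, by = c("compound_id", "year")) |>
    dplyr::mutate(n_gained = tidyr::replace_na(.data$n_gained, 0L)) |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::mutate(degree = cumsum(.data$n_gained)) |>
    dplyr::ungroup() |>
    dplyr::select("compound_id", "year", "degree")
  structure(out, horizon = horizon,
            class = c("promiscuity_series", class(tibble::tibble())))
}

series_horizon <- function(series) {
  h <- attr(series, "horizon", exact = TRUE)
  if (is.null(h)) max(series$year) else h
}

#' Summarise a promiscuity time course per compound
#'
#' Collapses a [promiscuity_series()] to one row per compound: the first
#' recorded year, the degree in that first year (which may exceed 1 when a
#' compound debuts against several targets), the final degree at the
#' horizon, and `delta` - the gain in target annotations between debut and
#' horizon. `delta = 0` means the compound's promiscuity stayed constant
#' over its entire activity history.
#'
#' @param series A `promiscuity_series` tibble.
#' @return A `promiscuity_profiles` tibble: `compound_id`, `first_year`,
#'   `first_degree`, `final_degree`, `delta`.
#' @export
promiscuity_profiles <- function(series) {
  assert_activity_cols(series, cols = c("compound_id", "year", "degree"),
                       arg = "series")
  horizon <- series_horizon(series)
  out <- series |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(
      first_year = min(.data$year),
      first_degree = .data$degree[which.min(.data$year)],
      final_degree = .data$degree[which.max(.data$year)],
      .groups = "drop"
    ) |>
    dplyr::mutate(delta = .data$final_degree - .data$first_degree)
  structure(out, horizon = horizon,
            class = c("promiscuity_profiles", class(tibble::tibble())))
}

#' Mean promiscuity degree per year
#'
#' Averages the cumulative promiscuity degree over all qualifying
#' compounds for each year. A compound qualifies in year `y` once its
#' first record has appeared (`first_year <= y`); years before the first
#' compound's debut are absent from the output.
#'
#' @param series A `promiscuity_series` tibble.
#' @param years Optional year vector to restrict the output to.
#' @return An `annual_promiscuity` tibble: `year`, `n_compounds`
#'   (qualifying compounds), `mean_degree` (full precision; report rounded
#'   to one decimal).
#' @export
#' @examples
#' annual_mean_promiscuity(promiscuity_series(worked_example_fixture()))
annual_mean_promiscuity <- function(series, years = NULL) {
  assert_activity_cols(series, cols = c("year", "degree"), arg = "series")
  out <- series |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      n_compounds = dplyr::n(),
      mean_degree = mean(.data$degree),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$year)
  if (!is.null(years)) out <- dplyr::filter(out, .data$year %in% as.integer(years))
  structure(out, class = c("annual_promiscuity", class(tibble::tibble())))
}

#' Promiscuity-gain histogram bins
#'
#' Bin labels for the delta-promiscuity histogram: single-unit bins for
#' gains of 0 through 5 targets, then `6-10`, `11-20`, `21-50` and `>50`.
#' The bins are disjoint and exhaustive over the non-negative integers.
#'
#' @return Character vector of the ten bin labels, in order.
#' @export
delta_bins <- function() {
  c("0", "1", "2", "3", "4", "5", "6-10", "11-20", "21-50", ">50")
}

#' Bin promiscuity gains
#'
#' @param delta Integer vector of non-negative promiscuity gains.
#' @return Factor over [delta_bins()].
#' @export
bin_delta <- function(delta) {
  if (any(delta < 0, na.rm = TRUE)) rlang::abort("`delta` must be non-negative.")
  cut(delta,
      breaks = c(-0.5, 0.5, 1.5, 2.5, 3.5, 4.5, 5.5, 10.5, 20.5, 50.5, Inf),
      labels = delta_bins())
}

new_delta_histogram <- function(rows) {
  structure(rows, total = sum(rows$count),
            class = c("delta_histogram", class(tibble::tibble())))
}

#' Histogram of per-compound promiscuity gains
#'
#' Assigns every compound to exactly one [delta_bins()] bin by its delta
#' (final minus first-year promiscuity degree) and counts compounds per
#' bin. The bin `"0"` collects compounds whose promiscuity stayed constant
#' over their whole activity history.
#'
#' @param x A `promiscuity_series` or `promiscuity_profiles` tibble.
#' @return A `delta_histogram` tibble (`bin`, `count`, all ten bins always
#'   present) whose counts sum to the number of compounds (attribute
#'   `"total"`).
#' @export
#' @examples
#' delta_histogram(promiscuity_series(worked_example_fixture()))
delta_histogram <- function(x) {
  if (inherits(x, "promiscuity_series") ||
      (!"delta" %in% names(x) && all(c("compound_id", "year", "degree") %in% names(x)))) {
    x <- promiscuity_profiles(x)
  }
  assert_activity_cols(x, cols = "delta", arg = "x")
  rows <- tibble::tibble(bin = bin_delta(x$delta)) |>
    dplyr::count(.data$bin, name = "count", .drop = FALSE) |>
    dplyr::mutate(bin = as.character(.data$bin))
  new_delta_histogram(rows)
}

#' Assemble a delta histogram from printed counts
#'
#' Builds a `delta_histogram` from per-bin compound counts already in hand
#' (e.g. a published summary table), enabling conservation checks and
#' constant-promiscuity fractions on them via [prop_constant()].
#'
#' @param counts Named numeric vector; names must be exactly
#'   [delta_bins()] (any order).
#' @return A `delta_histogram` tibble.
#' @export
#' @examples
#' as_delta_histogram(c(
#'   "0" = 151786, "1" = 1239, "2" = 469, "3" = 220, "4" = 102,
#'   "5" = 65, "6-10" = 130, "11-20" = 40, "21-50" = 9, ">50" = 2
#' ))
as_delta_histogram <- function(counts) {
  if (!setequal(names(counts), delta_bins()) || length(counts) != length(delta_bins())) {
    rlang::abort("`counts` must be named by exactly the ten delta_bins() labels.")
  }
  if (any(counts < 0)) rlang::abort("Bin counts must be non-negative.")
  rows <- tibble::tibble(
    bin = delta_bins(),
    count = as.integer(counts[delta_bins()])
  )
  new_delta_histogram(rows)
}

#' Fraction of compounds with constant promiscuity
#'
#' The proportion of compounds in the `"0"` bin of a delta histogram -
#' those whose promiscuity degree never increased after their first
#' recorded year.
#'
#' @param histogram A `delta_histogram`.
#' @return A proportion in \[0, 1\] (full precision; percentages are
#'   conventionally reported to one decimal).
#' @export
prop_constant <- function(histogram) {
  assert_activity_cols(histogram, cols = c("bin", "count"), arg = "histogram")
  total <- sum(histogram$count)
  if (total == 0) rlang::abort("Histogram is empty; fraction undefined.")
  histogram$count[histogram$bin == "0"] / total
}

#' Records of compounds that debuted in a given year
#'
#' Selects the activity-history cohort: all records (including later ones)
#' of exactly those compounds whose earliest release year equals
#' `first_year`. Cohorts for distinct debut years are disjoint and jointly
#' cover all compounds.
#'
#' @param x A data frame of activity records, all with a release year.
#' @param first_year Debut year defining the cohort (e.g. 1994 for a
#'   20-year activity history at a 2014 horizon).
#' @return A tibble of the cohort's records (possibly empty).
#' @export
cohort_subset <- function(x, first_year) {
  assert_activity_cols(x, cols = c("compound_id", "release_year"))
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) return(x)
  require_complete_years(x, "cohort_subset")
  debut <- x |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(first_year = min(.data$release_year), .groups = "drop")
  keep <- debut$compound_id[debut$first_year == as.integer(first_year)]
  dplyr::filter(x, .data$compound_id %in% keep)
}

#' Current mean promiscuity of a record set
#'
#' The average number of distinct targets per compound accumulated by the
#' horizon year - the "current" promiscuity level of the set. Equals the
#' [annual_mean_promiscuity()] value at the horizon over all compounds in
#' the data.
#'
#' @param x A non-empty data frame of activity records, all with a release
#'   year.
#' @param horizon Year at which to evaluate; defaults to the latest
#'   release year. Records after the horizon are ignored.
#' @return A single number (full precision; report rounded to one
#'   decimal).
#' @export
#' @examples
#' current_mean_promiscuity(worked_example_fixture())
current_mean_promiscuity <- function(x, horizon = NULL) {
  assert_activity_cols(x, cols = c("compound_id", "target_id", "release_year"))
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) rlang::abort("Cannot compute mean promiscuity of an empty record set.")
  require_complete_years(x, "current_mean_promiscuity")
  if (is.null(horizon)) horizon <- max(x$release_year)
  x <- dplyr::filter(x, .data$release_year <= as.integer(horizon))
  if (nrow(x) == 0) {
    rlang::abort("No records at or before the requested horizon.")
  }
  x |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(degree = dplyr::n_distinct(.data$target_id), .groups = "drop") |>
    dplyr::pull(.data$degree) |>
    mean()
}
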