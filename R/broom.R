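#' Tidy a validation report into one row per rejection reason
#'
#' @param x A `validation_report` from [read_activity_table()].
#' @param ... Unused.
#' @return A tibble with columns `reason` and `n`.
#' @exportS3Method generics::tidy
tidy.validation_report <- function(x, ...) {
  tibble::tibble(
    reason = names(x$rejection_reasons) %||% character(),
    n = unname(as.integer(x$rejection_reasons))
  )
}

#' One-row summary of a validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return A one-row tibble of the read / retained / rejected counts.
#' @exportS3Method generics::glance
glance.validation_report <- function(x, ...) {
  tibble::tibble(
    n_records_read = x$n_records_read,
    n_retained = x$n_retained,
    n_rejected = x$n_rejected,
    n_duplicates = x$n_duplicates,
    n_missing_release_year = x$n_missing_release_year
  )
}

#' One-row summary of a promiscuity time course
#'
#' @param x A `promiscuity_series` from [promiscuity_series()].
#' @param ... Unused.
#' @return A one-row tibble: number of compounds, horizon year, mean
#'   promiscuity degree at the horizon, and the fraction of compounds
#'   whose degree stayed constant.
#' @exportS3Method generics::glance
glance.promiscuity_series <- function(x, ...) {
  profiles <- promiscuity_profiles(x)
  tibble::tibble(
    n_compounds = nrow(profiles),
    horizon = series_horizon(x),
    mean_promiscuity = if (nrow(profiles) == 0) NA_real_ else mean(profiles$final_degree),
    prop_constant = if (nrow(profiles) == 0) NA_real_ else mean(profiles$delta == 0)
  )
}

#' One-row summary of a delta histogram
#'
#' @param x A `delta_histogram`.
#' @param ... Unused.
#' @return A one-row tibble: total compounds and the constant-promiscuity
#'   fraction.
#' @exportS3Method generics::glance
glance.delta_histogram <- function(x, ...) {
  tibble::tibble(
    total = sum(x$count),
    prop_constant = prop_constant(x)
  )
}

#' Tidy a growth table
#'
#' @param x A `growth_tbl`.
#' @param ... Unused.
#' @return A plain tibble with the entity kind as a column.
#' @exportS3Method generics::tidy
tidy.growth_tbl <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x),
                entity = attr(x, "entity", exact = TRUE) %||% NA_character_,
                .before = 1)
}
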