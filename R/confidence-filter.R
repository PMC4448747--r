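#' Comments that flag an inactive or inconclusive measurement
#'
#' Activity-comment phrases whose presence (case-insensitive containment
#' in the trimmed comment) marks a record as carrying no positive activity
#' evidence; such records are excluded from the high-confidence tier.
#'
#' @return Character vector of flag phrases.
#' @export
inactivity_comments <- function() c("inactive", "inconclusive", "not active")

comment_flagged <- function(comment) {
  x <- tolower(trimws(ifelse(is.na(comment), "", comment)))
  hit <- rep(FALSE, length(x))
  for (phrase in inactivity_comments()) {
    hit <- hit | grepl(phrase, x, fixed = TRUE)
  }
  hit
}

#' Flag records against the high-confidence predicates
#'
#' Adds one logical column per high-confidence predicate plus a conjunction
#' column `.high_confidence`, so every excluded record is attributable to
#' the predicate(s) it fails. The predicates (all must hold):
#'
#' * `hc_direct_assay` - assay relationship type is `"D"` (direct).
#' * `hc_top_confidence` - assay confidence score is 9, the highest
#'   target-assignment confidence.
#' * `hc_single_protein` - target type is `"SINGLE PROTEIN"`.
#' * `hc_human` - organism is `"Homo sapiens"`.
#' * `hc_ki_ic50` - measurement type is `"Ki"` or `"IC50"`.
#' * `hc_exact_relation` - measurement relation is `"="` (approximate
#'   relations `>`, `<`, `~` are disregarded).
#' * `hc_value_present` - a measurement value is recorded.
#' * `hc_comment_clean` - the activity comment contains none of
#'   [inactivity_comments()].
#'
#' @param x A data frame of activity records.
#' @return The records with the predicate columns appended.
#' @seealso [apply_high_confidence()]
#' @export
flag_high_confidence <- function(x) {
  assert_activity_cols(x)
  dplyr::mutate(
    tibble::as_tibble(x),
    hc_direct_assay = !is.na(.data$relationship_type) & .data$relationship_type == "D",
    hc_top_confidence = !is.na(.data$confidence_score) & .data$confidence_score == 9L,
    hc_single_protein = !is.na(.data$target_type) & .data$target_type == "SINGLE PROTEIN",
    hc_human = !is.na(.data$organism) & .data$organism == "Homo sapiens",
    hc_ki_ic50 = !is.na(.data$measurement_type) & .data$measurement_type %in% c("Ki", "IC50"),
    hc_exact_relation = !is.na(.data$measurement_relation) & .data$measurement_relation == "=",
    hc_value_present = !is.na(.data$measurement_value),
    hc_comment_clean = !comment_flagged(.data$activity_comment),
    .high_confidence = .data$hc_direct_assay & .data$hc_top_confidence &
      .data$hc_single_protein & .data$hc_human & .data$hc_ki_ic50 &
      .data$hc_exact_relation & .data$hc_value_present & .data$hc_comment_clean
  )
}

#' Select the high-confidence activity records
#'
#' Keeps only records measuring a direct interaction (relationship type
#' `"D"`, confidence score 9) with a human single-protein target through an
#' explicitly defined Ki or IC50 value (relation `"="`, value present) and
#' not flagged inactive/inconclusive in the activity comment. Predicates
#' apply per record: a compound enters the high-confidence set through its
#' conforming records while its non-conforming records are dropped.
#'
#' @param x A data frame of activity records.
#' @return A tibble of the conforming records (possibly empty). Idempotent,
#'   and always a subset of [apply_low_confidence()] on the same input.
#' @export
#' @examples
#' apply_high_confidence(worked_example_fixture())
apply_high_confidence <- function(x) {
  flagged <- flag_high_confidence(x)
  out <- dplyr::filter(flagged, .data$.high_confidence)
  dplyr::select(out, dplyr::all_of(activity_columns()))
}

#' Select the low-confidence activity records
#'
#' Keeps every record against a human single-protein target, regardless of
#' assay confidence, relationship type, measurement type, relation, value
#' or comment - the permissive counterpart of [apply_high_confidence()].
#'
#' @param x A data frame of activity records.
#' @return A tibble of the conforming records (possibly empty). Idempotent.
#' @export
apply_low_confidence <- function(x) {
  assert_activity_cols(x)
  dplyr::filter(
    tibble::as_tibble(x)[activity_columns()],
    !is.na(.data$target_type), .data$target_type == "SINGLE PROTEIN",
    !is.na(.data$organism), .data$organism == "Homo sapiens"
  )
}

#' Tally distinct entities in a filtered record set
#'
#' Counts distinct compounds, targets and assays plus total activity
#' records in a (typically confidence-filtered) record set - the audit
#' summary emitted alongside each filter application.
#'
#' @param x A data frame of activity records.
#' @param label Tier label for the report row, e.g. `"high"` or `"low"`.
#' @return A one-row tibble: `label`, `n_compounds`, `n_targets`,
#'   `n_assays`, `n_activities`.
#' @export
#' @examples
#' filter_report(apply_high_confidence(worked_example_fixture()), "high")
filter_report <- function(x, label) {
  assert_activity_cols(x, cols = c("compound_id", "target_id", "assay_id"))
  tibble::tibble(
    label = as.character(label),
    n_compounds = dplyr::n_distinct(x$compound_id),
    n_targets = dplyr::n_distinct(x$target_id),
    n_assays = dplyr::n_distinct(x$assay_id),
    n_activities = nrow(x)
  )
}
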