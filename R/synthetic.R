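#' Default final-target-count distribution
#'
#' Probability mass over a compound's final number of distinct targets:
#' mass `p_single` on one target and a steep power-law tail over 2-60,
#' emulating the heavy concentration of bioactivity databases at
#' single-target compounds.
#'
#' @param p_single Mass on exactly one target.
#' @return Named probability vector over `"1"` ... `"60"`.
#' @export
default_promiscuity_distribution <- function(p_single = 0.975) {
  if (p_single <= 0 || p_single > 1) {
    rlang::abort("`p_single` must be in (0, 1].")
  }
  k <- 2:60
  if (p_single == 1) {
    return(c("1" = 1))
  }
  tail <- k^-2.5
  tail <- tail / sum(tail) * (1 - p_single)
  stats::setNames(c(p_single, tail), as.character(c(1L, k)))
}

#' Default confidence-attribute mix
#'
#' Marginal probabilities for the per-record confidence attributes.
#' Attributes are drawn independently, so roughly 30% of records satisfy
#' all high-confidence predicates jointly under these defaults - the
#' approximate high-confidence share of release-dated human single-protein
#' activity records in large public bioactivity databases.
#'
#' @return Named list of probability vectors, one per record attribute,
#'   plus `value_missing` for measurement-value availability.
#' @export
default_confidence_mix <- function() {
  list(
    relationship_type = c("D" = 0.90, "B" = 0.10),
    confidence_score = c("9" = 0.80, "8" = 0.10, "7" = 0.05, "5" = 0.05),
    target_type = c("SINGLE PROTEIN" = 0.90, "PROTEIN COMPLEX" = 0.07,
                    "ORGANISM" = 0.03),
    organism = c("Homo sapiens" = 0.85, "Rattus norvegicus" = 0.10,
                 "Mus musculus" = 0.05),
    measurement_type = c("Ki" = 0.35, "IC50" = 0.45, "EC50" = 0.15,
                         "Potency" = 0.05),
    measurement_relation = c("=" = 0.80, ">" = 0.10, "<" = 0.07, "~" = 0.03),
    activity_comment = stats::setNames(
      c(0.95, 0.02, 0.02, 0.01),
      c("", "inactive", "Not Active", "inconclusive")
    ),
    value_missing = c("present" = 0.97, "missing" = 0.03)
  )
}

check_prob_vector <- function(v, field) {
  if (!is.numeric(v) || length(v) == 0 || is.null(names(v)) ||
      any(v < 0) || abs(sum(v) - 1) > 1e-9) {
    rlang::abort(sprintf(
      "Invalid generator config: `%s` must be a named probability vector summing to 1.",
      field
    ), class = "promtime_config_error")
  }
  invisible(v)
}

#' Configuration for the synthetic activity-record generator
#'
#' Defines the study conditions a generated dataset emulates: annual
#' compound influx that grows slowly and then steeply after a breakpoint
#' year (the shape of public bioactivity-database growth from 1976 to
#' 2014), a final-target-count distribution concentrated at one target,
#' a configurable mix of assay-confidence attributes, and repeated
#' measurements per compound-target pair. All randomness is driven by the
#' single `seed`.
#'
#' @param n_compounds Number of compounds to generate.
#' @param year_range First and last release year, default 1976-2014.
#' @param growth_model `"piecewise_exponential"` (slow linear ramp, then
#'   multiplicative annual growth after `breakpoint_year`) or `"linear"`.
#' @param breakpoint_year Year after which growth turns steep; default
#'   2006.
#' @param growth_rate Annual multiplier of the compound influx after the
#'   breakpoint; default 1.5.
#' @param promiscuity_distribution Named probability vector over final
#'   distinct-target counts; see [default_promiscuity_distribution()].
#' @param debut_multiplicity Probability that a compound destined for
#'   three or more targets debuts with more than one of them (compounds
#'   with two targets always debut with one, so that every multi-target
#'   compound gains at least one target after its debut).
#' @param confidence_mix Named list of probability vectors for the record
#'   attributes; see [default_confidence_mix()].
#' @param records_per_pair Named probability vector over the number of
#'   repeated measurements per compound-target pair.
#' @param seed Integer master seed.
#' @return A `generator_config` object (validated list).
#' @export
generator_config <- function(n_compounds = 1000,
                             year_range = c(1976L, 2014L),
                             growth_model = c("piecewise_exponential", "linear"),
                             breakpoint_year = 2006L,
                             growth_rate = 1.5,
                             promiscuity_distribution = default_promiscuity_distribution(),
                             debut_multiplicity = 0.1,
                             confidence_mix = default_confidence_mix(),
                             records_per_pair = c("1" = 0.7, "2" = 0.2, "3" = 0.1),
                             seed = 1L) {
  growth_model <- match.arg(growth_model)
  bad <- function(field, why) {
    rlang::abort(sprintf("Invalid generator config: `%s` %s.", field, why),
                 class = "promtime_config_error")
  }
  if (!is.numeric(n_compounds) || length(n_compounds) != 1 || n_compounds < 1) {
    bad("n_compounds", "must be a count >= 1")
  }
  if (length(year_range) != 2 || year_range[[1]] >= year_range[[2]]) {
    bad("year_range", "must be (start, end) with start < end")
  }
  if (breakpoint_year < year_range[[1]] || breakpoint_year > year_range[[2]]) {
    bad("breakpoint_year", "must lie within year_range")
  }
  if (!is.numeric(growth_rate) || growth_rate <= 0) {
    bad("growth_rate", "must be positive")
  }
  check_prob_vector(promiscuity_distribution, "promiscuity_distribution")
  pd_names <- suppressWarnings(as.integer(names(promiscuity_distribution)))
  if (anyNA(pd_names) || any(pd_names < 1)) {
    bad("promiscuity_distribution", "must be named by integer target counts >= 1")
  }
  if (debut_multiplicity < 0 || debut_multiplicity > 1) {
    bad("debut_multiplicity", "must be a probability in [0, 1]")
  }
  needed <- names(default_confidence_mix())
  if (!is.list(confidence_mix) || !all(needed %in% names(confidence_mix))) {
    bad("confidence_mix", sprintf("must be a list with elements %s",
                                  paste(needed, collapse = ", ")))
  }
  for (field in needed) {
    check_prob_vector(confidence_mix[[field]], paste0("confidence_mix$", field))
  }
  check_prob_vector(records_per_pair, "records_per_pair")
  if (anyNA(suppressWarnings(as.integer(names(records_per_pair))))) {
    bad("records_per_pair", "must be named by integer record counts")
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    bad("seed", "must be a single integer")
  }
  structure(
    list(
      n_compounds = as.integer(n_compounds),
      year_range = as.integer(year_range),
      growth_model = growth_model,
      breakpoint_year = as.integer(breakpoint_year),
      growth_rate = growth_rate,
      promiscuity_distribution = promiscuity_distribution,
      debut_multiplicity = debut_multiplicity,
      confidence_mix = confidence_mix,
      records_per_pair = records_per_pair,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config> %d compounds, years %d-%d, %s growth (breakpoint %d, rate %.2f), seed %d\n",
    x$n_compounds, x$year_range[[1]], x$year_range[[2]], x$growth_model,
    x$breakpoint_year, x$growth_rate, x$seed
  ))
  invisible(x)
}

# Relative weight of each year for compound debuts under the growth model.
debut_weights <- function(config) {
  years <- seq(config$year_range[[1]], config$year_range[[2]])
  ramp <- 1 + 0.08 * (years - years[[1]])
  if (config$growth_model == "linear") {
    return(ramp)
  }
  post <- years > config$breakpoint_year
  w <- ramp
  w[post] <- ramp[years == config$breakpoint_year] *
    config$growth_rate^(years[post] - config$breakpoint_year)
  w
}

sample_named <- function(v, n) {
  names(v)[sample.int(length(v), n, replace = TRUE, prob = v)]
}

# uniform integers in [lo, hi], elementwise over equal-length vectors
runif_int <- function(lo, hi) {
  lo + as.integer(floor(stats::runif(length(lo)) * (hi - lo + 1)))
}

#' Generate a synthetic longitudinal activity dataset with ground truth
#'
#' Simulates a ChEMBL-like record table under the conditions in a
#' [generator_config()]: each compound receives a debut year from the
#' growth model, a final target set sized from the promiscuity
#' distribution, accretion years for its non-debut targets drawn uniformly
#' from the years strictly after its debut, repeated measurements per
#' compound-target pair, and independently drawn confidence attributes per
#' record. By construction a compound's promiscuity stays constant
#' (`delta = 0`) exactly when it has a single target, so the configured
#' single-target mass is recoverable from the pipeline's delta histogram.
#' Output is deterministic given the seed.
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_activity`:
#'   \describe{
#'     \item{records}{Tibble of activity records (canonical columns), all
#'       with release years.}
#'     \item{truth}{Ground truth consistent with the records by
#'       construction: `compounds` (per-compound `first_year`,
#'       `n_targets`, `debut_degree`, `delta`, `targets` list-column) and
#'       `new_compounds_by_year`.}
#'   }
#' @export
#' @examples
#' sim <- generate_activity_data(generator_config(n_compounds = 50, seed = 7))
#' nrow(sim$records)
generate_activity_data <- function(config) {
  if (!inherits(config, "generator_config")) {
    rlang::abort("`config` must be created by generator_config().")
  }
  withr::with_seed(config$seed, {
    n <- config$n_compounds
    years <- seq(config$year_range[[1]], config$year_range[[2]])
    horizon <- config$year_range[[2]]
    w <- debut_weights(config)

    pd <- config$promiscuity_distribution
    k <- as.integer(sample_named(pd, n))
    compound_id <- sprintf("CPD%06d", seq_len(n))

    # debut years; multi-target compounds need room to accrete, so they
    # debut no later than horizon - 1
    debut <- integer(n)
    single <- k == 1L
    debut[single] <- years[sample.int(length(years), sum(single),
                                      replace = TRUE, prob = w)]
    if (any(!single)) {
      yy <- years[-length(years)]
      ww <- w[-length(w)]
      debut[!single] <- yy[sample.int(length(yy), sum(!single),
                                      replace = TRUE, prob = ww)]
    }

    # debut set size d: 1 unless a compound with >= 3 targets is drawn to
    # debut multi-target; always d <= k - 1 for multi-target compounds
    d <- rep(1L, n)
    elig <- k >= 3L
    if (any(elig)) {
      multi_debut <- elig & stats::runif(n) < config$debut_multiplicity
      d[multi_debut] <- runif_int(rep(2L, sum(multi_debut)), k[multi_debut] - 1L)
    }

    # target sets: distinct within compound, drawn from a shared pool
    n_pool <- max(60L, as.integer(ceiling(n / 100)))
    pool <- sprintf("TGT%05d", seq_len(n_pool))
    target_sets <- vector("list", n)
    target_sets[single] <- as.list(pool[sample.int(n_pool, sum(single), replace = TRUE)])
    for (i in which(!single)) {
      target_sets[[i]] <- pool[sample.int(n_pool, k[[i]])]
    }

    # first-contribution year per compound-target pair: the first d
    # targets appear at debut, the rest accrete strictly after it
    pairs <- tibble::tibble(
      compound_id = rep(compound_id, k),
      target_id = unlist(target_sets),
      is_debut = unlist(lapply(seq_len(n), function(i) seq_len(k[[i]]) <= d[[i]])),
      debut_year = rep(debut, k)
    )
    pairs$first_year <- ifelse(
      pairs$is_debut,
      pairs$debut_year,
      runif_int(pairs$debut_year + 1L, rep(horizon, nrow(pairs)))
    )

    # expand to records: every pair gets >= 1 record at its first year,
    # repeats fall uniformly between first year and horizon
    n_rec <- as.integer(sample_named(config$records_per_pair, nrow(pairs)))
    n_rec[n_rec < 1L] <- 1L
    rec <- pairs[rep(seq_len(nrow(pairs)), n_rec), c("compound_id", "target_id", "first_year")]
    is_repeat <- unlist(lapply(n_rec, function(m) c(FALSE, rep(TRUE, m - 1L))))
    rec$release_year <- rec$first_year
    if (any(is_repeat)) {
      rec$release_year[is_repeat] <- runif_int(
        rec$first_year[is_repeat], rep(horizon, sum(is_repeat))
      )
    }

    m <- nrow(rec)
    mix <- config$confidence_mix
    value <- signif(stats::rlnorm(m, meanlog = log(100), sdlog = 1.2), 4)
    value[sample_named(mix$value_missing, m) == "missing"] <- NA_real_

    records <- tibble::tibble(
      compound_id = rec$compound_id,
      target_id = rec$target_id,
      target_type = sample_named(mix$target_type, m),
      organism = sample_named(mix$organism, m),
      assay_id = NA_character_,
      relationship_type = sample_named(mix$relationship_type, m),
      confidence_score = as.integer(sample_named(mix$confidence_score, m)),
      measurement_type = sample_named(mix$measurement_type, m),
      measurement_relation = sample_named(mix$measurement_relation, m),
      activity_comment = sample_named(mix$activity_comment, m),
      release_year = as.integer(rec$release_year),
      measurement_value = value
    )

    # assays: a per-year pool sized to about a third of that year's
    # records, so assay counts grow with the data
    records <- records |>
      dplyr::group_by(.data$release_year) |>
      dplyr::mutate(assay_id = sprintf(
        "AS%d_%03d", .data$release_year,
        sample.int(max(1L, ceiling(dplyr::n() / 3)), dplyr::n(), replace = TRUE)
      )) |>
      dplyr::ungroup()

    records <- records |>
      dplyr::distinct() |>
      dplyr::arrange(.data$compound_id, .data$release_year,
                     .data$target_id, .data$assay_id)

    truth_compounds <- tibble::tibble(
      compound_id = compound_id,
      first_year = debut,
      n_targets = k,
      debut_degree = d,
      delta = k - d,
      targets = target_sets
    )
    truth <- list(
      compounds = truth_compounds,
      new_compounds_by_year = truth_compounds |>
        dplyr::count(year = .data$first_year, name = "n_new") |>
        dplyr::arrange(.data$year)
    )
    structure(list(records = records, truth = truth),
              class = "synthetic_activity")
  })
}

#' @export
print.synthetic_activity <- function(x, ...) {
  cat(sprintf(
    "<synthetic_activity> %d records over %d compounds, years %d-%d\n",
    nrow(x$records), nrow(x$truth$compounds),
    min(x$records$release_year), max(x$records$release_year)
  ))
  invisible(x)
}

high_confidence_defaults <- function(n) {
  tibble::tibble(
    target_type = rep("SINGLE PROTEIN", n),
    organism = "Homo sapiens",
    relationship_type = "D",
    confidence_score = 9L,
    measurement_type = "Ki",
    measurement_relation = "=",
    activity_comment = ""
  )
}

#' One-compound worked-example dataset
#'
#' A single compound measured against target A in 1990, targets B and C in
#' 2000, and target D in 2005, all through high-confidence-conforming
#' records. Its cumulative promiscuity degree therefore steps from 1
#' (1990) over 3 (2000) to 4 (2005) - the canonical hand-checkable case
#' for the cumulative time-course machinery.
#'
#' @return A tibble of four activity records.
#' @export
#' @examples
#' promiscuity_series(worked_example_fixture())
worked_example_fixture <- function() {
  base <- high_confidence_defaults(4)
  tibble::tibble(
    compound_id = "CPD-EX-1",
    target_id = c("TGT-A", "TGT-B", "TGT-C", "TGT-D"),
    target_type = base$target_type,
    organism = base$organism,
    assay_id = sprintf("AS-EX-%d", 1:4),
    relationship_type = base$relationship_type,
    confidence_score = base$confidence_score,
    measurement_type = base$measurement_type,
    measurement_relation = base$measurement_relation,
    activity_comment = base$activity_comment,
    release_year = c(1990L, 2000L, 2000L, 2005L),
    measurement_value = c(12.5, 45, 230, 7.8)
  )
}

#' One-compound constant-promiscuity dataset
#'
#' A single compound that debuts against `n_targets` targets in
#' `first_year` and never gains another - the pattern of the large
#' majority of bioactive compounds, whose promiscuity degree stays
#' constant from first report onward (delta 0).
#'
#' @param n_targets Number of targets at debut (>= 1).
#' @param first_year Debut year.
#' @return A tibble of `n_targets` high-confidence-conforming records.
#' @export
#' @examples
#' delta_histogram(promiscuity_series(
#'   constant_promiscuity_fixture(2, 1993), horizon = 2014
#' ))
constant_promiscuity_fixture <- function(n_targets, first_year = 1993L) {
  if (!is.numeric(n_targets) || length(n_targets) != 1 || n_targets < 1) {
    rlang::abort("Invalid config: `n_targets` must be a count >= 1.",
                 class = "promtime_config_error")
  }
  n_targets <- as.integer(n_targets)
  base <- high_confidence_defaults(n_targets)
  tibble::tibble(
    compound_id = sprintf("CPD-CONST-%d-%d", n_targets, as.integer(first_year)),
    target_id = sprintf("TGT-C%02d", seq_len(n_targets)),
    target_type = base$target_type,
    organism = base$organism,
    assay_id = sprintf("AS-C-%d", seq_len(n_targets)),
    relationship_type = base$relationship_type,
    confidence_score = base$confidence_score,
    measurement_type = base$measurement_type,
    measurement_relation = base$measurement_relation,
    activity_comment = base$activity_comment,
    release_year = as.integer(first_year),
    measurement_value = 10 * seq_len(n_targets)
  )
}
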