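# Construct canonical activity-record tibbles for tests. Defaults conform
# to every high-confidence predicate; override any column to break one.
make_records <- function(compound_id, target_id, release_year, ...) {
  n <- max(length(compound_id), length(target_id), length(release_year))
  defaults <- tibble::tibble(
    compound_id = rep_len(compound_id, n),
    target_id = rep_len(target_id, n),
    target_type = "SINGLE PROTEIN",
    organism = "Homo sapiens",
    assay_id = sprintf("AS-%03d", seq_len(n)),
    relationship_type = "D",
    confidence_score = 9L,
    measurement_type = "Ki",
    measurement_relation = "=",
    activity_comment = "",
    release_year = as.integer(rep_len(release_year, n)),
    measurement_value = as.double(seq_len(n))
  )
  overrides <- list(...)
  for (col in names(overrides)) {
    defaults[[col]] <- rep_len(overrides[[col]], n)
  }
  defaults[promtime::activity_columns()]
}

# Random small dataset mixing conforming and non-conforming attributes;
# all release years present. Relies on the caller's RNG state.
random_dataset <- function(n_records = 30, years = 1990:2010,
                           n_compounds = 8, n_targets = 6, n_assays = 5) {
  make_records(
    compound_id = sprintf("C%02d", sample.int(n_compounds, n_records, replace = TRUE)),
    target_id = sprintf("T%02d", sample.int(n_targets, n_records, replace = TRUE)),
    release_year = sample(years, n_records, replace = TRUE),
    assay_id = sprintf("A%02d", sample.int(n_assays, n_records, replace = TRUE)),
    target_type = sample(c("SINGLE PROTEIN", "PROTEIN COMPLEX"), n_records,
                         replace = TRUE, prob = c(0.8, 0.2)),
    organism = sample(c("Homo sapiens", "Rattus norvegicus"), n_records,
                      replace = TRUE, prob = c(0.8, 0.2)),
    relationship_type = sample(c("D", "B"), n_records, replace = TRUE, prob = c(0.85, 0.15)),
    confidence_score = sample(c(9L, 8L, 5L), n_records, replace = TRUE, prob = c(0.8, 0.1, 0.1)),
    measurement_type = sample(c("Ki", "IC50", "EC50"), n_records, replace = TRUE),
    measurement_relation = sample(c("=", ">", "<", "~"), n_records,
                                  replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1)),
    activity_comment = sample(c("", "", "", "inactive", "Not Active"), n_records, replace = TRUE),
    measurement_value = ifelse(stats::runif(n_records) < 0.9,
                               signif(stats::rlnorm(n_records, log(100), 1), 4), NA_real_)
  )
}
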