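# Independent brute-force recounts of the time-course statistics: for
# each compound and year the target set is rebuilt from scratch by
# scanning all records, with no shared code with the package internals.

oracle_series <- function(rec, horizon = max(rec$release_year)) {
  out <- list()
  for (cpd in sort(unique(rec$compound_id))) {
    sub <- rec[rec$compound_id == cpd & rec$release_year <= horizon, ]
    if (nrow(sub) == 0) next
    fy <- min(sub$release_year)
    years <- fy:horizon
    degree <- vapply(
      years,
      function(y) length(unique(sub$target_id[sub$release_year <= y])),
      integer(1)
    )
    out[[cpd]] <- data.frame(compound_id = cpd, year = years, degree = degree)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  tibble::as_tibble(df)
}

oracle_growth <- function(rec, entity) {
  id <- switch(entity,
               compounds = rec$compound_id,
               targets = rec$target_id,
               assays = rec$assay_id,
               activities = seq_len(nrow(rec)))
  years <- min(rec$release_year):max(rec$release_year)
  n_new <- vapply(years, function(y) {
    sum(vapply(split(rec$release_year, id),
               function(ys) min(ys) == y, logical(1)))
  }, integer(1))
  tibble::tibble(year = years, n_new = n_new, n_cumulative = cumsum(n_new))
}

oracle_annual_mean <- function(rec, horizon = max(rec$release_year)) {
  ser <- oracle_series(rec, horizon)
  years <- sort(unique(ser$year))
  tibble::tibble(
    year = years,
    n_compounds = vapply(years, function(y) sum(ser$year == y), integer(1)),
    mean_degree = vapply(years, function(y) mean(ser$degree[ser$year == y]), double(1))
  )
}

# independent bin assignment, written as a plain decision chain
oracle_bin <- function(delta) {
  vapply(delta, function(d) {
    if (d <= 5) as.character(d)
    else if (d <= 10) "6-10"
    else if (d <= 20) "11-20"
    else if (d <= 50) "21-50"
    else ">50"
  }, character(1))
}

oracle_delta_histogram <- function(rec, horizon = max(rec$release_year)) {
  ser <- oracle_series(rec, horizon)
  bins <- c("0", "1", "2", "3", "4", "5", "6-10", "11-20", "21-50", ">50")
  deltas <- vapply(split(ser, ser$compound_id), function(s) {
    s$degree[s$year == max(s$year)] - s$degree[s$year == min(s$year)]
  }, integer(1))
  lab <- oracle_bin(deltas)
  tibble::tibble(
    bin = bins,
    count = vapply(bins, function(b) sum(lab == b), integer(1))
  )
}
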