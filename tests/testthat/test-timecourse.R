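test_that("growth_table counts entities once, in their earliest year, with zero-filled gaps", {
  rec <- make_records(c("C1", "C1", "C2"), c("T1", "T1", "T2"),
                      c(1990L, 2000L, 1990L))
  g <- growth_table(rec, "compounds")
  expect_equal(g$year, 1990:2000)
  expect_equal(g$n_new[g$year == 1990], 2L)
  expect_true(all(g$n_new[g$year > 1990] == 0L))
  expect_equal(g$n_cumulative, rep(2L, 11))
  # activities count every record in its own year
  a <- growth_table(rec, "activities")
  expect_equal(a$n_new[a$year %in% c(1990, 2000)], c(2L, 1L))
  expect_equal(max(a$n_cumulative), 3L)
})

test_that("growth_table handles single records and empty input", {
  one <- growth_table(make_records("C1", "T1", 1995), "compounds")
  expect_equal(tibble::as_tibble(one),
               tibble::tibble(year = 1995L, n_new = 1L, n_cumulative = 1L),
               ignore_attr = TRUE)
  empty <- growth_table(make_records("C1", "T1", 1995)[0, ], "targets")
  expect_equal(nrow(empty), 0)
})

test_that("cumulative counts are non-decreasing and end at the distinct-entity count", {
  set.seed(7)
  for (i in 1:10) {
    d <- random_dataset(n_records = sample(10:80, 1))
    for (kind in c("compounds", "targets", "assays", "activities")) {
      g <- growth_table(d, kind)
      expect_true(all(diff(g$n_cumulative) >= 0))
      expect_equal(g$n_cumulative, cumsum(g$n_new))
      n_entities <- switch(kind,
                           compounds = dplyr::n_distinct(d$compound_id),
                           targets = dplyr::n_distinct(d$target_id),
                           assays = dplyr::n_distinct(d$assay_id),
                           activities = nrow(d))
      expect_equal(max(g$n_cumulative), n_entities)
    }
  }
})

test_that("fold_increase is the cumulative ratio, 1.0 at identical years, and guards its domain", {
  g <- as_growth_table(data.frame(year = 1976:1978, n_new = c(10L, 30L, 60L)), "compounds")
  expect_equal(fold_increase(g, 1976, 1978), 10)
  expect_equal(fold_increase(g, 1977, 1977), 1.0)
  expect_error(fold_increase(g, 1970, 1978), "not present")
  zero <- as_growth_table(data.frame(year = 1976:1977, n_new = c(0L, 5L)), "compounds")
  expect_error(fold_increase(zero, 1976, 1977), "zero")
})

test_that("the worked example steps from 1 over 3 to 4 targets", {
  ser <- promiscuity_series(worked_example_fixture(), horizon = 2014)
  deg <- function(y) ser$degree[ser$year == y]
  expect_equal(deg(1990), 1L)
  expect_equal(deg(1999), 1L)
  expect_equal(deg(2000), 3L)
  expect_equal(deg(2005), 4L)
  expect_equal(deg(2014), 4L)
  prof <- promiscuity_profiles(ser)
  expect_equal(prof$first_year, 1990L)
  expect_equal(prof$delta, 3L)
})

test_that("re-measuring a known target never changes the degree", {
  rec <- make_records("C1", "T1", c(1990L, 2005L), assay_id = c("A1", "A2"))
  ser <- promiscuity_series(rec, horizon = 2014)
  expect_true(all(ser$degree == 1L))
  expect_equal(promiscuity_profiles(ser)$delta, 0L)
})

test_that("a single dated record yields a flat degree-1 series to the horizon", {
  ser <- promiscuity_series(make_records("C1", "T1", 1993), horizon = 2014)
  expect_equal(ser$year, 1993:2014)
  expect_true(all(ser$degree == 1L))
})

test_that("per-compound degree is non-decreasing on random datasets", {
  set.seed(2024)
  for (i in 1:20) {
    d <- random_dataset(n_records = sample(10:100, 1))
    ser <- promiscuity_series(d)
    drops <- ser |>
      dplyr::group_by(compound_id) |>
      dplyr::summarise(ok = all(diff(degree) >= 0))
    expect_true(all(drops$ok))
  }
})

test_that("annual mean averages the degree over compounds already seen", {
  rec <- make_records(c("C1", "C2", "C2"), c("T1", "T2", "T3"), 2000,
                      assay_id = c("A1", "A2", "A3"))
  m <- annual_mean_promiscuity(promiscuity_series(rec, horizon = 2000))
  expect_equal(m$mean_degree, 1.5)
  expect_equal(m$n_compounds, 2L)
  # compound seen earlier keeps qualifying in later years
  rec2 <- make_records(c("C1", "C2"), c("T1", "T2"), c(1990L, 2000L))
  m2 <- annual_mean_promiscuity(promiscuity_series(rec2, horizon = 2000))
  expect_equal(m2$n_compounds[m2$year == 1995], 1L)
  expect_equal(m2$n_compounds[m2$year == 2000], 2L)
  expect_false(any(m2$year < 1990))
})

test_that("annual mean matches a brute-force recount on a constructed toy", {
  # degrees {1, 1, 4} in 1990 -> mean 2.0
  rec <- make_records(
    c("C1", "C2", "C3", "C3", "C3", "C3"),
    c("T1", "T2", "T1", "T2", "T3", "T4"),
    1990L, assay_id = sprintf("A%d", 1:6)
  )
  m <- annual_mean_promiscuity(promiscuity_series(rec, horizon = 1990))
  expect_equal(m$mean_degree, 2.0)
  expect_equal(tibble::as_tibble(m), oracle_annual_mean(rec), ignore_attr = TRUE)
})

test_that("delta binning respects every bin boundary", {
  expect_equal(as.character(bin_delta(c(0, 1, 5, 6, 7, 10, 11, 20, 21, 50, 51, 1000))),
               c("0", "1", "5", "6-10", "6-10", "6-10", "11-20", "11-20",
                 "21-50", "21-50", ">50", ">50"))
  expect_error(bin_delta(-1), "non-negative")
})

test_that("delta_histogram assigns each compound to exactly one bin", {
  profiles <- tibble::tibble(
    compound_id = sprintf("C%d", 1:4),
    first_year = 1990L, first_degree = 1L,
    final_degree = c(1L, 1L, 2L, 52L),
    delta = c(0L, 0L, 1L, 51L)
  )
  h <- delta_histogram(profiles)
  expect_equal(h$count[h$bin == "0"], 2L)
  expect_equal(h$count[h$bin == "1"], 1L)
  expect_equal(h$count[h$bin == ">50"], 1L)
  expect_equal(sum(h$count), 4L)
  expect_equal(h$bin, delta_bins())
})

test_that("histogram construction from printed counts validates and summarises", {
  counts <- stats::setNames(c(5, 1, 0, 0, 0, 0, 2, 0, 0, 1), delta_bins())
  h <- as_delta_histogram(counts)
  expect_equal(sum(h$count), 9L)
  expect_equal(prop_constant(h), 5 / 9)
  expect_error(as_delta_histogram(counts[-1]), "delta_bins")
})

test_that("cohorts select exactly the compounds debuting in the given year", {
  rec <- make_records(
    c("C1", "C1", "C2", "C2", "C3"),
    c("T1", "T2", "T1", "T3", "T2"),
    c(1994L, 2001L, 1993L, 1994L, 2004L),
    assay_id = sprintf("A%d", 1:5)
  )
  c94 <- cohort_subset(rec, 1994)
  expect_setequal(c94$compound_id, "C1")
  expect_equal(nrow(c94), 2)              # later records retained
  expect_false("C2" %in% c94$compound_id) # first seen 1993, despite a 1994 record
  expect_equal(nrow(cohort_subset(rec, 1999)), 0)
})

test_that("cohorts partition the compound set across debut years", {
  set.seed(5)
  d <- random_dataset(n_records = 80)
  debut_years <- sort(unique(
    dplyr::summarise(dplyr::group_by(d, compound_id),
                     y = min(release_year))$y
  ))
  cohorts <- lapply(debut_years, function(y) unique(cohort_subset(d, y)$compound_id))
  expect_equal(sum(lengths(cohorts)), dplyr::n_distinct(d$compound_id))
  expect_equal(anyDuplicated(unlist(cohorts)), 0)
})

test_that("current mean promiscuity equals the annual mean at the horizon", {
  rec <- make_records(
    c("C1", "C2", "C3", "C4", "C4", "C4"),
    c("T1", "T1", "T2", "T1", "T2", "T3"),
    c(1990L, 1995L, 2000L, 1990L, 1999L, 2005L),
    assay_id = sprintf("A%d", 1:6)
  )
  expect_equal(current_mean_promiscuity(rec, horizon = 2014), 1.5)  # degrees {1,1,1,3}
  m <- annual_mean_promiscuity(promiscuity_series(rec, horizon = 2014))
  expect_equal(m$mean_degree[m$year == 2014], 1.5)
  expect_error(current_mean_promiscuity(rec[0, ]), "empty")
})
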