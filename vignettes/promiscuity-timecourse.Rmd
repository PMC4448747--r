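---
title: "Methods: quantifying promiscuity progression from longitudinal activity records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying promiscuity progression from longitudinal activity records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promtime)
```

## The model

The unit of observation is an *activity record*: one measured
compound–target interaction from one assay, carrying confidence metadata
(assay relationship type, assay confidence score, target type, organism,
measurement type/relation/value, free-text comment) and a release date.
All analyses reduce release dates to calendar years; public bioactivity
databases are curated and released on an annual rhythm, and no statistic in
this package benefits from finer resolution, so input dates of the form
`YYYY-MM-DD` are truncated to `YYYY` at load time.

A compound's *promiscuity degree* in year $y$ is the number of distinct
targets over all of its records released up to and including $y$:

$$\mathrm{deg}(c, y) \;=\; \bigl|\{\, t(r) : r \in R(c),\; \mathrm{year}(r) \le y \,\}\bigr|.$$

The degree is a non-decreasing step function of $y$, defined from the
compound's first recorded year (its *debut*) to a global *horizon*. A
target contributes from its earliest year onward; re-measuring a known
target never changes the degree. Three summaries are built on it:

* the **annual mean** $\bar{d}(y)$, averaging $\mathrm{deg}(c, y)$ over all
  compounds whose debut is $\le y$;
* the per-compound gain
  $\Delta = \mathrm{deg}(c, \mathrm{horizon}) - \mathrm{deg}(c, \mathrm{debut})$,
  histogrammed over the bins $0, 1, \dots, 5$, $6\!-\!10$, $11\!-\!20$,
  $21\!-\!50$, $>\!50$ (disjoint and exhaustive over the non-negative
  integers);
* **cohorts**: the compounds debuting in a fixed year, followed to the
  horizon.

Note that $\Delta$ is measured against the *debut degree*, which can exceed
one when a compound is first reported against several targets at once; such
a compound still has $\Delta = 0$ if nothing is added later.

Identity is nominal throughout: a compound is its identifier string, and
two database entries with different identifiers are different compounds.
No structure-based canonicalization is attempted — structures are outside
the package's scope.

## Confidence tiers

Promiscuity estimates are notoriously sensitive to data quality, so two
record filters are built in:

* **high** — direct assays (relationship type `"D"`) at the top
  target-assignment confidence (score 9) on human (`"Homo sapiens"`)
  single-protein targets, measured as an explicitly defined Ki or IC50:
  relation `"="`, value present, and an activity comment free of
  inactivity flags. Approximate relations (`>`, `<`, `~`) are disregarded.
* **low** — every record against a human single-protein target, with no
  further criteria.

The high predicates strictly strengthen the low ones, so the high-tier
record set is a subset of the low-tier set on any input (property-tested).
Predicates apply per record, not per compound: a compound joins the
high-confidence set through its conforming records while its other records
are dropped.

Two choices here were genuinely open and are resolved as follows. Comment
matching is case-insensitive *containment* of the phrases `"inactive"`,
`"inconclusive"`, `"not active"` in the trimmed comment: comments are free
text (`"Not Active"`, `"declared inconclusive"`), and the intent of the
filter is to drop anything flagged as carrying no positive activity
evidence, so exact-phrase equality would be too narrow. Second, the
comment filter belongs to the high tier only; the low tier is deliberately
permissive ("regardless of confidence and measurement type" is its whole
definition), so it applies no comment or relation screening at all.

## Validation and I/O

`read_activity_table()` screens every row and never drops silently: each
rejected row is tallied under a named reason (unparseable or out-of-range
confidence score or year, missing identifier, negative value), and
byte-identical duplicate rows are removed and counted, so that
`rows read = retained + rejected` always holds. Exact duplicates would
inflate activity-record growth counts; near-duplicates (same
compound–target pair, different values or assays) are retained, since the
degree counts distinct targets and is unaffected. Records without release
dates are kept at load, counted, and excluded explicitly by
`exclude_missing_release_year()` before any time-course operation, which
requires a year on every record. Missing values serialize as empty strings;
writing then reading is the identity on valid tables.

## Numerical and degenerate-input conventions

* All means and ratios are kept at full precision internally; one-decimal
  rounding (growth folds, percentages, mean degrees) is a reporting
  convention only.
* The horizon defaults to the latest release year in the data. Records
  dated after an explicitly requested horizon are ignored rather than
  rejected.
* Growth tables span the full year range of the record set, with zero
  filled in for years without new entries; the empty record set yields an
  empty table, not an error.
* An annual-mean year with no qualifying compounds is absent from the
  output rather than reported as `NaN`; the mean of an empty record set is
  an error.
* Histogram bins use ASCII hyphens (`"6-10"`) so labels survive CSV/TSV
  round trips.
* Fold increases require a positive denominator; a zero cumulative count
  at the base year is a domain error.

## The synthetic-data generator

`generate_activity_data()` emulates the statistical shape of a
release-dated bioactivity database over 1976–2014 so that every pipeline
stage can be exercised against known ground truth:

* **Growth.** Compound debut years are drawn from a slow linear ramp that
  switches to multiplicative growth (default rate 1.5 per year) after a
  breakpoint (default 2006) — the characteristic slow-then-steep influx of
  public medicinal-chemistry data. A linear-only model is available as a
  control.
* **Promiscuity.** Final distinct-target counts follow a categorical
  distribution with, by default, 97.5% mass on a single target and a
  steep power-law tail over 2–60 — bioactivity databases are heavily
  concentrated at single-target compounds.
* **Accretion.** A multi-target compound debuts with a strict subset of
  its final targets (more than one only with probability
  `debut_multiplicity`, and only when it has at least three targets) and
  accretes the rest at years drawn uniformly from the interval strictly
  after its debut; multi-target compounds therefore debut no later than
  horizon − 1. This is a deliberate identifiability choice: it makes
  $\Delta = 0$ hold exactly for the single-target compounds and for no
  others, so the configured single-target mass is recoverable from the
  pipeline's Δ histogram up to binomial sampling error — the package's
  parameter-recovery check. No empirical accretion model is claimed; the
  pipeline's correctness must not depend on this choice, and the
  brute-force oracle tests hold under arbitrary accretion patterns.
* **Confidence attributes** are drawn independently per record from
  configurable marginals whose defaults make roughly 30% of records
  satisfy all high-confidence predicates jointly. Repeated measurements
  per compound–target pair (default mix of 1–3 records) land uniformly
  between the pair's first year and the horizon; assay identifiers are
  drawn from per-year pools sized to about a third of that year's records
  so assay counts grow with the data.
* **Determinism.** All randomness flows from the single `seed` through one
  generator stream; the same configuration reproduces the records byte for
  byte.

What the generator does **not** emulate: chemical structures, realistic
potency-value distributions, correlation between a compound's debut year
and its eventual promiscuity beyond the shrinking accretion window, and
curation artifacts such as retrospective re-dating. Passing tests on
synthetic data therefore demonstrate the correctness of the counting and
filtering machinery under known ground truth — not that any particular
real database exhibits a particular promiscuity level.

## Testing strategy and problem sizes

Each time-course statistic is checked exactly against an independent
brute-force oracle that rebuilds every compound's target set from scratch
by scanning all records, over 200 random datasets of up to 100 records;
filter properties (subset relation, idempotence) run over a further 100
random datasets; parameter recovery uses 10,000 compounds with a
single-target mass of 0.985 and a three-standard-error binomial band.
These sizes give the property checks broad coverage of edge cases (single
years, debut-with-many-targets, repeated measurements) while the whole
suite stays fast enough to run on every change.

## Limitations

* Promiscuity is counted per compound (targets per compound); the dual
  view, compounds per target, is out of scope.
* Target identity is the annotation string; orthologs, mutants or
  target-family groupings are not merged.
* No statistical hypothesis testing is performed anywhere — the outputs
  are descriptive counts and means.
* The 2014-style final year of a real database is typically incomplete;
  that is a property of the data, not a code path, and no proration is
  attempted.
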