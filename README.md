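# promtime

Time-resolved promiscuity analysis of bioactive compound records.

Compound **promiscuity** — the ability of a small molecule to specifically
interact with multiple targets — is the molecular basis of polypharmacology.
Its apparent magnitude depends strongly on the confidence level of the
activity data used to count target annotations, and it can only be judged in
context by watching how target annotations accumulate as bioactivity
databases grow. `promtime` is for cheminformaticians and data miners who
work with ChEMBL-like activity-record tables (one row per
compound–target–assay measurement, with release dates) and want to quantify
promiscuity progression over time under explicit data-confidence criteria.

## What it computes

For a record set *R* and a year *y*, a compound *c*'s **promiscuity degree**
is the cumulative distinct-target count

> deg(c, y) = |{ target(r) : r ∈ R(c), year(r) ≤ y }|,

a non-decreasing step function from the compound's first recorded year to
the analysis horizon. On top of it the package derives:

- **Confidence tiers.** A *high-confidence* filter keeps records of direct
  assays (relationship type `"D"`, confidence score 9) on human
  single-protein targets with explicitly defined Ki/IC50 values (relation
  `"="`, value present, no "inactive"/"inconclusive"/"not active" comment);
  a *low-confidence* filter keeps any human single-protein record.
- **Growth tables.** Per-year new and cumulative counts of compounds,
  targets, assays and activity records (entities count once, in the year of
  their earliest record), plus fold increases between years.
- **Annual mean promiscuity.** mean of deg(c, y) over all compounds already
  seen by year *y*.
- **Δ-promiscuity histograms.** Per-compound gain
  Δ = deg(c, horizon) − deg(c, first year), binned as
  0, 1, …, 5, 6–10, 11–20, 21–50, >50; Δ = 0 means promiscuity stayed
  constant over the compound's whole activity history.
- **Debut-year cohorts.** Compounds first recorded in a given year
  (e.g. 1994 ⇒ a 20-year history at a 2014 horizon) and their current mean
  promiscuity.
- **Synthetic data.** A seeded generator of ChEMBL-like longitudinal record
  tables with known ground truth (debut years, target-accretion times,
  confidence-attribute mix), so the whole pipeline is testable without any
  database download.

## Worked example

```r
library(promtime)

sim <- generate_activity_data(generator_config(n_compounds = 2000, seed = 42))
rec <- sim$records                       # 3044 records, years 1976-2014

filter_report(apply_high_confidence(rec), "high")
#>   label n_compounds n_targets n_assays n_activities
#> 1 high          833        60      654          993

ser <- promiscuity_series(apply_high_confidence(rec))
glance(ser)
#>   n_compounds horizon mean_promiscuity prop_constant
#> 1         833    2014             1.06         0.981

tail(annual_mean_promiscuity(ser), 3)
#>    year n_compounds mean_degree
#> 1  2012         436        1.02
#> 2  2013         576        1.03
#> 3  2014         833        1.06
```

Of the 3044 simulated records, 993 survive the strict confidence criteria,
covering 833 compounds. Their mean promiscuity at the 2014 horizon is 1.06
targets per compound and 98.1% of them never gained a target annotation
after their debut — the heavy concentration at constant, single-target
promiscuity that real bioactivity databases show. `delta_histogram(ser)`
bins the per-compound gains, `growth_table(rec, "compounds")` tabulates the
annual influx (slow growth, then steep growth after 2006), and
`autoplot()` turns any of these results into a ggplot.

`run_full_analysis(records, tier = "both", out_dir = "results/")` runs the
whole workflow (filter reports, four growth tables, annual means, profiles,
Δ histograms, cohort means, JSON manifest) per tier; `inst/cli/promtime.R`
exposes the same stages as shell subcommands (`run`, `filter`, `growth`,
`promiscuity`, `cohort`, `simulate`).

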