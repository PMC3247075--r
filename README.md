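# srcensus

Census-style descriptive analysis of systematic review databases.

Collections of systematic reviews such as the *Cochrane Database of
Systematic Reviews* hold, inside each review's 'Data and analyses'
section, a four-level hierarchy: pair-wise **comparisons** of two
interventions, **outcomes** (each outcome is one forest plot and one
candidate meta-analysis), **subgroups** of studies within a plot, and
study-level **data rows** in one of four forms — binary 2×2 counts,
continuous means/SDs, generic estimate ± standard error, and
observed-minus-expected event counts with variance. Meta-epidemiological
surveys of such collections must first clean this hierarchy (drop
protocols and withdrawn reviews, strip the phantom zero-pattern records
that legacy forest-plot software stored for studies contributing no
data, deduplicate studies repeated across overlapping subgroups, and
keep only plots with at least two distinct studies) and then classify
and summarise what remains. `srcensus` implements that whole pipeline
for anyone studying the anatomy of evidence synthesis: methodologists
calibrating simulation studies, statisticians developing small-sample
meta-analysis methods, and meta-researchers characterising review
collections.

The package provides:

* **Data model & interchange** — `sr_database()` holds the hierarchy in
  relational form; `load_database()` / `save_database()` read and write
  a canonical nested JSON format and a flat one-row-per-study CSV, with
  full invariant validation (`validate_sr_database()`).
* **Curation** — `curate()` composes `filter_reviews()` (protocols,
  withdrawn reviews, methodology group), phantom removal
  (`is_phantom_study()`), within-plot first-occurrence deduplication
  (`deduplicate_plot()`) and the two-study rule
  (`select_eligible_meta_analyses()`), producing conservation-checked
  flow ledgers at review, meta-analysis and study level, plus
  `detect_structural_anomalies()` for data-entry mistakes.
* **Taxonomies** — controlled vocabularies (11 medical specialties, 15
  active + 2 control intervention categories, 23 outcome categories
  with priority resolution via `resolve_outcome_category()`), the
  15×5 comparison classification `classify_comparison()` and the
  collapse maps onto 5 intervention-comparison groups, 11 outcome
  groups and 3 data-type groups. All shipped as an editable YAML
  configuration.
* **Census engine** — `count_by()` one-way tables with the two
  percentage dialects of published census tables (`render_percent()`),
  `crosstab_interventions()` with conserved margins and
  `collapse_crosstab()`, `per_review_summary()` and
  `grouped_quantiles()` (type-7 quantiles, i.e. linear interpolation at
  position (n−1)p+1), and a tie-aware `wilcoxon_rank_sum()` that uses
  exact enumeration for n₁+n₂ ≤ 20 and a tie-corrected,
  continuity-corrected normal approximation otherwise.
* **Synthetic generator** — `generate_database(default_config(...))`
  emits reproducible synthetic databases calibrated to the published
  marginals of the January 2008 CDSR issue (median 3 studies per
  meta-analysis with quartiles 2–6, log-normal sample sizes with
  quartiles 44/91/210, data-type mixture 66/30/4%, published
  specialty/intervention/outcome marginals), with controlled phantom
  and duplicate contamination and exact ground truth for it.

## Worked example

```r
library(srcensus)

gen <- generate_database(default_config(n_reviews = 300, seed = 42))
report <- curate(gen$db)
report$review_ledger
#> <flow_ledger>
#>                      stage records_in excluded
#>                   protocol        300      110
#>                  withdrawn        190        1
#>          methodology group        189        1
#>  no eligible meta-analyses        188        0

cur <- report$curated
cur
#> (188 eligible reviews, 1827 meta-analyses, 8703 retained study rows)

grouped_quantiles(cur, "studies_per_meta_analysis", "data_type_group")
#>         group    n p50 p75 p90   p99 max
#> 1 Dichotomous 1237   3   5  10 24.64  39
#> 2  Continuous  516   3   5  10 22.70  50
#> 3       Mixed   74   3   7  15 25.08  28

compare_study_counts(cur, "All-cause mortality")
#> Wilcoxon rank-sum: U = 81578 (normal-approximation), two-sided p = 0.007457
```

The ledger shows each eligibility stage with its exclusions (110 of the
300 generated records were protocols, etc.); the quantile table shows
that eligible meta-analyses are small — median 3 studies — in every
data-type group, and the rank-sum comparison asks whether all-cause
mortality meta-analyses draw on more studies than the rest (here, as in
real collections, they tend to).

`run_pipeline()` (or the thin CLI in `inst/cli/srcensus.R`, with
subcommands `simulate`, `curate`, `validate`, `summarize`) runs the
whole chain on a database file and writes the curated database, the
flow ledgers and the six standard summary tables — specialty counts,
the intervention cross-tabulation, outcome counts, review composition,
and the stratified quantile tables for meta-analysis size and study
sample size.

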