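---
title: "Methods: curating and summarising a systematic-review database"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curating and summarising a systematic-review database}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srcensus)
```

## The unit of analysis

`srcensus` treats one forest plot — one outcome under one pair-wise
intervention comparison — as one candidate meta-analysis, whether or not
the review authors chose to display a pooled result. A database is a
hierarchy of reviews → comparisons → outcomes → subgroups → study rows,
held internally in relational form (four linked data frames) because
every census operation is a query over that structure; the nested JSON
interchange format restores the hierarchical view. Study rows carry one
of four payloads: binary 2×2 counts, continuous per-arm
n/mean/SD, a generic estimate with standard error, or
observed-minus-expected events with variance. Generic and O–E data are
summarised together as "mixed" outcome data, since both are effect-level
rather than arm-level records.

## Eligibility and cleaning

Curation applies, in order:

1. **Review filter** — protocols, withdrawn reviews and methodology-group
   reviews are removed, each under its own ledger stage.
2. **Phantom removal** — legacy forest-plot software stored a row for
   every study listed in a plot even when it contributed no data,
   leaving recognisable zero-patterns at an apparent sample size of 2:
   binary `0/1` events in each arm; continuous total n = 2 with means
   and SDs of 0; O–E and variance both 0. Size-2 rows with any other
   pattern are genuine and kept. Two points here are deliberate package
   choices. First, the classic patterns cover three data types only; we
   extend the same logic to generic rows (estimate 0, standard error 0)
   because the storage mechanism is identical, and expose
   `curation_options(generic_phantoms = FALSE)` to disable the
   extension. Second, "sample size 2" for the continuous pattern is read
   as one participant per arm, with `continuous_phantom_allocation =
   "any_split"` available for the looser reading (0+2 splits).
3. **Deduplication** — subgroups within a plot need not be mutually
   exclusive, so the same study can appear twice; only the first
   occurrence in document order is kept. Identity is exact string match
   after whitespace trimming: labels such as "Smith 2001a" and
   "Smith 2001b" are different studies, a known source of missed
   duplicates in any automated pass.
4. **Two-study rule** — plots left with fewer than two distinct studies
   are dropped, then comparisons and reviews left empty.

Phantoms are removed before deduplication so that a duplicate of a
phantom cannot shadow a genuine removal; the final two-study test is
order-invariant either way. Every stage appears in a `flow_ledger`
whose constructor enforces conservation (records entering stage k+1 =
records entering k − excluded at k), so a ledger that fails to account
for a record is a hard error, not a silent discrepancy. Curation is
idempotent: re-running it on its own output excludes nothing.

Structural data-entry mistakes (sibling outcomes with identical names —
typically subgroups typed in as separate outcomes — missing outcome
names, and payload fields inconsistent with the declared data type) are
*detected* (`detect_structural_anomalies()`) but never repaired: in real
collections these require human judgement. A study row missing the
required payload fields for its declared type is instead a load-time
validation error, because no census quantity can be computed from it.

## Classification

Labels are inputs, not inferences: the package validates them against
controlled vocabularies but never assigns them from free text. The
vocabularies (11 medical specialties, 15 active + 2 control intervention
categories, 23 outcome categories) ship as editable YAML. Two
configuration points deserve justification:

* **Outcome priority order.** When an outcome could fall under several
  categories it takes the category highest on the priority list. No
  published order exists for the 23 categories, so the shipped default
  is a documented assumption: mortality and morbidity categories first
  (they are the most objectively defined), broad sign/symptom categories
  last (they are catch-alls). Reproduction work should supply its order
  explicitly.
* **Residual outcome groups.** The 23 categories collapse onto 11
  summary groups. Nine groups are determined by the published group
  labels; membership of the two residual groups ("semi-objective" and
  "subjective") is not fully recoverable from published sources, whose
  group sizes also carry small internal inconsistencies (±1 on
  recomputation, and the published stratified table omits the "Other"
  category from its outcome block entirely — its group rows sum to 94
  fewer than the total). The shipped default assigns
  withdrawals/dropouts, internal and external structure, consumption,
  the non-mortality composite and satisfaction with care to the
  semi-objective group, and quality of life, pain, mental health,
  surgical/device success and "Other" to the subjective group; this
  choice makes the group sizes implied by the published one-way
  marginals agree with the published group sizes to within the same ±1.
  The map is total (every category maps somewhere), surjective onto the
  11 groups, and editable.

Comparison classification maps (active, comparator) onto the 15×5 table
— comparator kinds Control, Placebo, Pharmacological, same-category
non-pharm, different-category non-pharm — with the pharmacological ×
same-category cell structurally excluded, and onto the five-way
collapse used for stratified summaries. Control and Placebo are kept
distinct in data (review authors conflate them inconsistently), with
the combined view provided by the collapse.

## Summaries and numerical conventions

* **Quantiles** use linear interpolation between order statistics at
  position (n−1)p+1 (`stats::quantile` type 7). On integer count data
  this lands on an order statistic for most quartiles, giving integer
  medians/quartiles; it is also R's default, so results are directly
  comparable with interactive work.
* **Percent rendering** follows the two dialects of published census
  tables: the integer dialect renders a zero count as "0%", any nonzero
  share strictly below 1% as "<1%", and everything else as the nearest
  integer (half away from zero); the one-decimal dialect shows shares
  below 1% with one decimal place. Counts always re-sum exactly even
  when rendered percentages do not.
* **Cross-tabs** carry their margins; marginal conservation is an
  invariant of the container, and structurally excluded cells contribute
  zero to every margin.
* **Rank-sum test.** `wilcoxon_rank_sum()` uses mid-ranks for ties. For
  n₁+n₂ ≤ 20 it enumerates all group assignments of the pooled values,
  which is valid under ties (the base library's exact path is not); the
  suite cross-checks this path against an independent pairwise-comparison
  oracle and, on untied data, against the base library. Otherwise it
  uses the normal approximation with tie-corrected variance and a 0.5
  continuity correction, identical to the base library's approximate
  path. Exhaustive enumeration of every untied 8+8 configuration puts
  the worst-case deviation of that approximation from exact enumeration
  at 0.0109 (in the central region of the U distribution); the package
  therefore documents agreement to within 0.011 at the enumeration
  boundary, improving with sample size. Degenerate input (all values
  identical) returns p = 1 rather than 0/0.
* **Repeated studies.** A study contributing to several meta-analyses is
  counted once per appearance in sample-size summaries; building a
  distinct-study view would require identity resolution across plots
  and reviews, which study labels do not support.

## The synthetic generator

Real review collections of this kind are proprietary, so the package
ships a generator whose defaults *are* the documented study conditions,
calibrated once to published marginals and not revisited:

* branching: comparisons per review 1 + Geometric(p = 0.61), capped at
  23 (so 61% of reviews hold a single comparison, matching the published
  share, with quartiles 1/1/2); outcomes per comparison
  1 + NB(size = 0.44, μ = 4.15), capped at 68 (quartiles 1/3/6);
* studies per plot 2 + NB(size = 0.37, μ = 2.85), capped at 294
  (quantiles 3/6/10 at 50/75/90%, 99th percentile 26 against a published
  28 — the closest fit a two-parameter tail allows);
* sample size log-normal with meanlog = ln 91 and
  sdlog = (ln 210 − ln 44)/(2 × 0.6745) ≈ 1.159, rounded to integers
  ≥ 2 (quartiles ≈ 44/91/210);
* data-type mixture 0.663/0.297/0.040 (dichotomous/continuous/mixed),
  the mixed share split 3:1 between generic and O–E as a package
  assumption (no published split exists);
* labels drawn from the published specialty, intervention-pair and
  outcome marginals, independently across dimensions (only marginals
  are published; a joint override can be passed via
  `category_marginals`).

The parametric families are package choices — published sources report
only empirical quantiles — and each is swappable through the
`dist_spec` abstraction. Contamination is applied last: with probability
`phantom_rate` a plot receives one appended phantom in its declared
data type's pattern; with probability `duplicate_rate` a multi-subgroup
plot re-inserts its first study into a later subgroup. Genuine draws
that would collide with a phantom pattern (a binary study drawn at 1+1
with zero events) are nudged off it, so ground truth is exact and the
suite can demand set-equality between injected and removed rows.
Randomness uses one root seed with per-review substreams, so extending
a database never perturbs existing reviews.

What the generator does **not** emulate: joint dependence between
specialty, intervention and outcome; dependence between study size and
meta-analysis size; the extreme maxima of real collections (tails are
capped); realistic review/comparison text; and the per-review
composition extremes (comparisons and meta-analyses per review are
calibrated only through their marginal branching distributions, so
their joint quantiles are emergent rather than matched). Passing tests
on synthetic data therefore demonstrate the correctness of the
pipeline's rules and the recoverability of calibrated marginals, not
fidelity to any real collection's joint structure.

## Problem sizes

The test suite and the acceptance script run the generator at 25–300
reviews per database (a 250-review clean run yields ≳ 2000 eligible
meta-analyses and ≈ 10,000 study rows, enough for the calibrated median
of 3 studies per plot to be recovered exactly and the sample-size
median to land within a few percent of 91), 20 seeds for contamination
accounting, and exhaustive enumeration at the rank-sum test's 8+8
boundary. The in-paper cross-tabulation algebra is exact and runs in
milliseconds.

## Known limitations

* No parser for real review-manager XML exports; the interchange
  formats are this package's own documented schema.
* Classification is validation-only by design; captions are not mined.
* The CSV interchange cannot represent containers without study rows
  (they are dropped with a warning on save); JSON is lossless.
* Identity of studies across plots and reviews is out of reach of
  exact-label matching, so cross-plot overlap is not modelled or
  measured.
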