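Package: srcensus
Title: Census-Style Descriptive Analysis of Systematic Review Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-epidemiological censuses of systematic review
    collections structured like the Cochrane Database of Systematic Reviews.
    Provides a relational data model for the 'Data and analyses' hierarchy of
    a review collection (reviews, pair-wise comparisons, forest-plot outcomes,
    subgroups and study-level rows in four data types), an eligibility and
    cleaning pipeline with a full audit ledger (review-level exclusions,
    phantom-record removal, within-plot deduplication, the two-study rule),
    controlled vocabularies for medical specialty, intervention and outcome
    with priority resolution and collapse maps, a descriptive summarisation
    engine (one-way tables, intervention cross-tabulations, grouped quantile
    summaries, a tie-aware Wilcoxon rank-sum test), and a calibrated synthetic
    database generator with recorded contamination ground truth so the whole
    pipeline can be exercised without access to proprietary review data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
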