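vocabs <- default_vocabularies()

test_that("percent rendering follows the two table dialects", {
  # integer dialect: nonzero shares under 1% get the "<1%" label
  expect_equal(render_percent(186, 22453), "<1%")
  expect_equal(render_percent(0, 22453), "0%")
  expect_equal(render_percent(4027, 22453), "18%")
  expect_equal(render_percent(4321, 22453), "19%")
  expect_equal(render_percent(5571, 22453), "25%")
  expect_equal(render_percent(14105, 22453), "63%")
  expect_equal(render_percent(380, 22453), "2%")   # 1.69% rounds up
  expect_equal(render_percent(241, 22453), "1%")   # 1.07% rounds down
  # one-decimal dialect for small shares
  expect_equal(render_percent(94, 22453, "one_decimal_small"), "0.4%")
  expect_equal(render_percent(29, 22453, "one_decimal_small"), "0.1%")
  expect_equal(render_percent(3639, 22453, "one_decimal_small"), "16%")
  expect_error(render_percent(1, 0), "positive")
  expect_error(render_percent(5, 3), "exceeds")
})

test_that("census quantiles interpolate at position (n-1)p + 1", {
  expect_equal(census_quantile(c(1, 2, 3, 4), 0.25), 1.75)
  expect_equal(census_quantile(c(2, 2, 3, 6, 10), 0.5), 3)  # odd-length median
  x <- c(4, 1, 7, 7, 2, 9, 3)
  q <- census_quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9, 1))
  expect_true(all(diff(q) >= 0))          # monotone in p
  expect_true(all(q >= min(x) & q <= max(x)))
})

test_that("one-way tables include zero categories and re-sum to the total", {
  db <- tiny_db()
  t1 <- count_by(db, "specialty", vocabs)
  expect_equal(nrow(t1), 11)
  expect_equal(sum(t1$count), n_meta_analyses(db))
  expect_equal(t1$count[t1$category == "Cancer"], 2)
  expect_equal(t1$count[t1$category == "Urogenital"], 2)
  expect_equal(sum(t1$count == 0), 9)

  t3 <- count_by(db, "outcome_category", vocabs, "one_decimal_small")
  expect_equal(nrow(t3), 23)
  expect_equal(sum(t3$count), 4)

  tg <- count_by(db, "data_type_group", vocabs)
  expect_equal(sum(tg$count), 4)
  expect_equal(tg$count[tg$category == "Mixed"], 2)

  # empty database: all zeros, percentages shown as em-dash
  t0 <- count_by(sr_database(), "specialty", vocabs)
  expect_true(all(t0$count == 0))
  expect_true(all(t0$percent == "—"))

  # missing labels abort with the plot named
  bad <- tiny_db()
  bad$reviews$specialty_label[1] <- NA
  expect_error(count_by(bad, "specialty", vocabs), "missing specialty_label")
})

test_that("intervention cross-tab conserves margins and excludes the n/a cell", {
  db <- tiny_db()
  ct <- crosstab_interventions(db, vocabs)
  expect_equal(ct$counts["Pharmacological", "Placebo"], 2)
  expect_equal(ct$counts["Surgical", "same-category non-pharm"], 2)
  expect_true(is.na(ct$counts["Pharmacological", "same-category non-pharm"]))
  expect_equal(ct$grand_total, 4)
  expect_equal(sum(ct$row_totals), ct$grand_total)
  expect_equal(sum(ct$col_totals), ct$grand_total)
  expect_equal(unname(ct$row_totals["Pharmacological"]), 2)

  # margins conserve on synthetic data too
  gen <- generate_database(test_config(60, 11))
  cur <- curate(gen$db)$curated
  ct2 <- crosstab_interventions(cur, vocabs)
  expect_equal(sum(ct2$row_totals), n_meta_analyses(cur))
  expect_equal(sum(ct2$col_totals), n_meta_analyses(cur))
  expect_equal(rowSums(ct2$counts, na.rm = TRUE), ct2$row_totals)
  # collapsing to the 5 comparison groups preserves the grand total
  expect_equal(sum(collapse_crosstab(ct2, vocabs$intervention)),
               ct2$grand_total)
})

test_that("review-composition summaries use the right units", {
  # 2 reviews with 1 and 3 comparisons -> median comparisons per review 2
  rv <- data.frame(review_id = c("A", "B"), title = "t", review_group = "g",
                   status = "full", is_methodology_group = FALSE,
                   specialty_label = NA)
  cp <- data.frame(review_id = c("A", "B", "B", "B"),
                   comparison_id = c("C1", "C1", "C2", "C3"),
                   name = "c", active_intervention_label = NA,
                   comparator_label = NA)
  oc <- data.frame(review_id = cp$review_id, comparison_id = cp$comparison_id,
                   outcome_id = "O1", name = "o", data_type = "generic",
                   totals_displayed = TRUE, outcome_category_label = NA)
  db <- sr_database(rv, cp, oc)
  s <- per_review_summary(db)
  expect_equal(s$p50[s$measure == "comparisons per review"], 2)

  # review with comparisons holding 2 and 4 plots -> 6 meta-analyses
  oc2 <- data.frame(review_id = "A",
                    comparison_id = rep(c("C1", "C2"), c(2, 4)),
                    outcome_id = paste0("O", 1:6), name = "o",
                    data_type = "generic", totals_displayed = TRUE,
                    outcome_category_label = NA)
  db2 <- sr_database(rv[1, ], data.frame(
    review_id = "A", comparison_id = c("C1", "C2"), name = "c",
    active_intervention_label = NA, comparator_label = NA), oc2)
  s2 <- per_review_summary(db2)
  ma <- s2[s2$measure == "meta-analyses per review", ]
  expect_equal(ma$p50, 6)

  # single comparison with 5 outcomes: degenerate five-number summary
  db3 <- sr_database(rv[1, ],
                     data.frame(review_id = "A", comparison_id = "C1",
                                name = "c", active_intervention_label = NA,
                                comparator_label = NA),
                     data.frame(review_id = "A", comparison_id = "C1",
                                outcome_id = paste0("O", 1:5), name = "o",
                                data_type = "generic", totals_displayed = TRUE,
                                outcome_category_label = NA))
  s3 <- per_review_summary(db3)
  oc_row <- s3[s3$measure == "outcomes per comparison", ]
  expect_equal(unlist(oc_row[c("min", "p50", "max")], use.names = FALSE),
               c(5, 5, 5))

  expect_equal(nrow(per_review_summary(sr_database())), 0)
})

test_that("grouped quantiles partition the units and report missing sizes", {
  gen <- generate_database(test_config(80, 5))
  cur <- curate(gen$db)$curated

  overall <- grouped_quantiles(cur, "studies_per_meta_analysis", "none")
  expect_equal(overall$n, n_meta_analyses(cur))
  for (g in c("data_type_group", "specialty", "collapsed5", "outcome_group11")) {
    qs <- grouped_quantiles(cur, "studies_per_meta_analysis", g)
    expect_equal(sum(qs$n), n_meta_analyses(cur))  # partition property
    ok <- !is.na(qs$max)
    expect_true(all(qs$p50[ok] <= qs$p75[ok]))
    expect_true(all(qs$max[ok] >= qs$p99[ok]))
  }

  sz <- grouped_quantiles(cur, "study_sample_size", "data_type_group")
  st <- study_table(cur)
  expect_equal(sum(sz$n), sum(!is.na(st$sample_size)))
  expect_equal(attr(sz, "n_missing"), sum(is.na(st$sample_size)))
})

test_that("rank-sum test matches enumeration, symmetry and the library check", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$method, "exact")
  expect_equal(r$p_two_sided, 0.1)

  # identical multisets: central U, p = 1
  r2 <- wilcoxon_rank_sum(c(1, 2, 2, 5), c(1, 2, 2, 5))
  expect_equal(r2$U, 4 * 4 / 2)
  expect_equal(r2$p_two_sided, 1)

  # tie-aware exact p agrees with the independent pairwise-comparison oracle
  set.seed(31)
  for (i in 1:5) {
    x <- sample(1:6, 5, replace = TRUE)
    y <- sample(1:6, 6, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(x, y, method = "exact")$p_two_sided,
                 oracle_exact_p(x, y), tolerance = 1e-12)
  }

  # untied data: exact p agrees with the base library's exact test
  set.seed(7)
  x <- rnorm(7); y <- rnorm(8) + 0.5
  expect_equal(wilcoxon_rank_sum(x, y, method = "exact")$p_two_sided,
               suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value),
               tolerance = 1e-12)

  # normal approximation tracks exact enumeration for balanced 8 + 8
  set.seed(19)
  x <- round(rnorm(8, 5, 2)); y <- round(rnorm(8, 6, 2))
  pe <- wilcoxon_rank_sum(x, y, method = "exact")$p_two_sided
  pn <- wilcoxon_rank_sum(x, y, method = "normal")$p_two_sided
  expect_lt(abs(pe - pn), 0.01)

  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("outcome-group comparison wrapper splits plots correctly", {
  gen <- generate_database(test_config(80, 23))
  cur <- curate(gen$db)$curated
  res <- compare_study_counts(cur, "All-cause mortality")
  expect_true(res$p_two_sided >= 0 && res$p_two_sided <= 1)
  pt <- plot_table(cur)
  g11 <- collapse_outcome_group(pt$outcome_category_label,
                                vocabs$outcome_group11)
  n1 <- sum(g11 == "All-cause mortality")
  expect_true(res$U <= n1 * (nrow(pt) - n1))
  expect_error(compare_study_counts(cur, "Nonexistent group"), "unknown")
})
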