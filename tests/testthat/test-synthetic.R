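test_that("generation is deterministic and stable under extension", {
  cfg <- test_config(30, 99)
  a <- generate_database(cfg)
  b <- generate_database(cfg)
  expect_identical(a, b)

  # per-review substreams: adding reviews never perturbs earlier ones
  big <- generate_database(test_config(40, 99))
  expect_equal(big$db$reviews[1:30, ], a$db$reviews, ignore_attr = TRUE)
  expect_equal(big$db$studies[big$db$studies$review_id %in%
                                a$db$reviews$review_id, ],
               a$db$studies, ignore_attr = TRUE)
})

test_that("degenerate and clean configurations behave as documented", {
  empty <- generate_database(test_config(0, 1))
  expect_equal(n_reviews(empty$db), 0)
  expect_equal(nrow(empty$ground_truth$phantoms), 0)

  clean <- generate_database(test_config(50, 4, phantom_rate = 0,
                                         duplicate_rate = 0))
  report <- curate(clean$db)
  expect_equal(sum(report$study_ledger$excluded), 0)
  expect_equal(n_study_rows(report$curated), n_study_rows(clean$db))
})

test_that("default calibration matches its published targets", {
  cfg <- default_config()
  mix <- cfg$data_type_mixture
  expect_equal(unname(mix["dichotomous"]), 14886 / 22453, tolerance = 1e-3)
  expect_equal(unname(mix["continuous"]), 6672 / 22453, tolerance = 1e-3)
  expect_equal(unname(mix["generic"] + mix["oe_variance"]), 895 / 22453,
               tolerance = 1e-3)
  expect_equal(sum(mix), 1, tolerance = 1e-9)

  # log-normal scale from the printed sample-size quartiles 44/91/210
  expect_equal(cfg$sample_size$sdlog,
               (log(210) - log(44)) / (2 * qnorm(0.75)), tolerance = 1e-3)
  expect_equal(cfg$sample_size$meanlog, log(91), tolerance = 1e-9)

  marg <- cfg$category_marginals
  expect_equal(sum(marg$specialty), 1, tolerance = 1e-9)
  expect_equal(sum(marg$outcome), 1, tolerance = 1e-9)
  expect_equal(sum(marg$intervention, na.rm = TRUE), 1, tolerance = 1e-9)

  expect_error(generator_config(10, data_type_mixture = c(dichotomous = 1)),
               "data_type_mixture")
  expect_error(generator_config(10, phantom_rate = 1.5), "probabilities")
  expect_error(generator_config(-1), "non-negative")
})

test_that("emitted databases validate and respect structural minima", {
  gen <- generate_database(test_config(60, 8, phantom_rate = 0.3,
                                       duplicate_rate = 0.3))
  expect_silent(validate_sr_database(gen$db))
  expect_equal(nrow(detect_structural_anomalies(gen$db)), 0)
  expect_equal(nrow(validate_labels(gen$db)), 0)

  # at least two genuine studies per plot before contamination
  pt <- plot_table(gen$db)
  injected <- rbind(gen$ground_truth$phantoms, gen$ground_truth$duplicates)
  inj_per_plot <- table(factor(
    paste(injected$review_id, injected$comparison_id, injected$outcome_id),
    levels = paste(pt$review_id, pt$comparison_id, pt$outcome_id)))
  expect_true(all(pt$n_studies - as.integer(inj_per_plot) >= 2))
  expect_equal(sum(pt$n_studies),
               unname(gen$ground_truth$pre_contamination["studies"]) +
                 nrow(injected))
})

test_that("curation removes exactly the injected contamination", {
  key <- function(df) paste(df$review_id, df$comparison_id, df$outcome_id,
                            df$study_id, df$position)
  for (seed in c(2, 13, 77)) {
    gen <- generate_database(test_config(40, seed, phantom_rate = 0.3,
                                         duplicate_rate = 0.3))
    report <- curate(gen$db)
    expect_setequal(key(report$removed$phantoms),
                    key(gen$ground_truth$phantoms))
    expect_setequal(key(report$removed$duplicates),
                    key(gen$ground_truth$duplicates))
    expect_equal(nrow(report$removed$underfilled), 0)
  }
})
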