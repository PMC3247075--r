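make_review <- function(id, status = "full", methodology = FALSE) {
  data.frame(review_id = id, title = "t", review_group = "g", status = status,
             is_methodology_group = methodology, specialty_label = NA)
}

test_that("review filter drops protocols, withdrawn and methodology reviews", {
  db <- sr_database(reviews = rbind(
    make_review("R1", "protocol"),
    make_review("R2", "withdrawn"),
    make_review("R3"), make_review("R4"), make_review("R5")
  ))
  res <- filter_reviews(db)
  expect_equal(n_reviews(res$db), 3)
  expect_equal(sum(res$ledger$excluded), 2)
  expect_equal(sum(res$ledger$excluded > 0), 2)  # two distinct reasons hit

  # identity on an all-eligible database
  clean <- sr_database(reviews = rbind(make_review("R1"), make_review("R2")))
  res2 <- filter_reviews(clean)
  expect_equal(res2$db$reviews, clean$reviews, ignore_attr = TRUE)
  expect_true(all(res2$ledger$excluded == 0))

  # empty database
  res3 <- filter_reviews(sr_database())
  expect_equal(n_reviews(res3$db), 0)
  expect_true(all(res3$ledger$records_in == 0))

  meth <- sr_database(reviews = rbind(make_review("R1"),
                                      make_review("R2", methodology = TRUE)))
  expect_equal(filter_reviews(meth)$db$reviews$review_id, "R1")
})

test_that("phantom patterns are recognised per data type and nothing else", {
  d <- function(e1, t1, e2, t2)
    data.frame(data_type = "dichotomous", study_id = "s",
               events_1 = e1, total_1 = t1, events_2 = e2, total_2 = t2)
  expect_true(is_phantom_study(d(0, 1, 0, 1)))
  expect_false(is_phantom_study(d(1, 1, 0, 1)))  # size 2, different pattern
  expect_false(is_phantom_study(d(0, 2, 0, 2)))

  cont <- data.frame(data_type = "continuous", study_id = "s",
                     n_1 = 1, mean_1 = 0, sd_1 = 0,
                     n_2 = 1, mean_2 = 0, sd_2 = 0)
  expect_true(is_phantom_study(cont))
  cont$mean_1 <- 0.5
  expect_false(is_phantom_study(cont))
  # allocation reading is configurable: 0+2 split only under "any_split"
  skew <- data.frame(data_type = "continuous", study_id = "s",
                     n_1 = 0, mean_1 = 0, sd_1 = 0,
                     n_2 = 2, mean_2 = 0, sd_2 = 0)
  expect_false(is_phantom_study(skew))
  expect_true(is_phantom_study(
    skew, curation_options(continuous_phantom_allocation = "any_split")))

  oe <- data.frame(data_type = "oe_variance", study_id = "s",
                   o_minus_e = 0, variance = 0)
  expect_true(is_phantom_study(oe))
  expect_false(is_phantom_study(
    data.frame(data_type = "oe_variance", study_id = "s",
               o_minus_e = -2.1, variance = 4)))

  gen <- data.frame(data_type = "generic", study_id = "s",
                    estimate = 0, standard_error = 0)
  expect_true(is_phantom_study(gen))
  expect_false(is_phantom_study(
    gen, curation_options(generic_phantoms = FALSE)))
})

test_that("deduplication keeps first occurrences across subgroups", {
  db <- dich_plot_db(
    list(c(1, 10, 1, 10), c(2, 12, 1, 12), c(1, 10, 1, 10), c(0, 9, 1, 9)),
    study_ids = c("A", "B", "A", "C"),
    subgroups = c("Subgroup 1", "Subgroup 1", "Subgroup 2", "Subgroup 2")
  )
  plot <- get_plot(db, "R1", "C1", "O1")
  res <- deduplicate_plot(plot)
  expect_equal(res$removed, 1)
  expect_equal(res$plot$studies$study_id, c("A", "B", "C"))
  expect_equal(res$plot$studies$subgroup,
               c("Subgroup 1", "Subgroup 1", "Subgroup 2"))

  # idempotent, and identity when ids are distinct
  again <- deduplicate_plot(res$plot)
  expect_equal(again$removed, 0)
  expect_equal(again$plot$studies, res$plot$studies, ignore_attr = TRUE)

  # near-identical labels are distinct studies
  ab <- dich_plot_db(list(c(1, 10, 1, 10), c(1, 10, 1, 10)),
                     study_ids = c("Smith 2001a", "Smith 2001b"))
  expect_equal(deduplicate_plot(get_plot(ab, "R1", "C1", "O1"))$removed, 0)
})

test_that("eligibility selection composes the rules in order", {
  # a single-study plot is discarded
  one <- dich_plot_db(list(c(1, 10, 1, 10)))
  expect_equal(n_meta_analyses(select_eligible_meta_analyses(one)$curated), 0)

  # two studies of which one is phantom -> one remains -> plot discarded
  ph <- dich_plot_db(list(c(1, 10, 1, 10), c(0, 1, 0, 1)))
  rep_ph <- select_eligible_meta_analyses(ph)
  expect_equal(n_meta_analyses(rep_ph$curated), 0)
  expect_equal(nrow(rep_ph$removed$phantoms), 1)

  # three entries, one duplicating another -> two distinct remain -> kept
  dup <- dich_plot_db(
    list(c(1, 10, 1, 10), c(2, 12, 1, 12), c(1, 10, 1, 10)),
    study_ids = c("A", "B", "A"),
    subgroups = c("Subgroup 1", "Subgroup 1", "Subgroup 2")
  )
  rep_dup <- select_eligible_meta_analyses(dup)
  expect_equal(n_meta_analyses(rep_dup$curated), 1)
  expect_equal(n_study_rows(rep_dup$curated), 2)
})

test_that("ledgers conserve counts and curation is idempotent", {
  gen <- generate_database(test_config(n_reviews = 80, seed = 42,
                                       phantom_rate = 0.2,
                                       duplicate_rate = 0.2))
  report <- curate(gen$db)
  for (led in list(report$review_ledger, report$meta_analysis_ledger,
                   report$study_ledger)) {
    expect_s3_class(led, "flow_ledger")  # constructor enforces conservation
    carried <- led$records_in - led$excluded
    if (nrow(led) > 1) {
      expect_equal(carried[-nrow(led)], led$records_in[-1])
    }
  }
  # total retained + total excluded = total in
  expect_equal(n_study_rows(report$curated) + sum(report$study_ledger$excluded),
               report$study_ledger$records_in[1])

  # running the pipeline on its own output changes nothing
  report2 <- curate(report$curated)
  expect_equal(report2$curated, report$curated, ignore_attr = TRUE)
  expect_true(all(report2$review_ledger$excluded == 0))
  expect_true(all(report2$study_ledger$excluded == 0))

  # curated database satisfies the eligibility invariants
  cur <- report$curated
  expect_true(all(cur$reviews$status == "full"))
  expect_false(any(phantom_flags(study_table(cur))))
  expect_false(any(duplicated(paste(cur$studies$review_id,
                                    cur$studies$comparison_id,
                                    cur$studies$outcome_id,
                                    cur$studies$study_id))))
  expect_true(all(plot_table(cur)$n_studies >= 2))
  expect_true(all(cur$reviews$review_id %in% cur$outcomes$review_id))
})

test_that("structural anomaly detection flags without modifying", {
  clean <- tiny_db()
  expect_equal(nrow(detect_structural_anomalies(clean)), 0)

  db <- tiny_db()
  db$outcomes$name[db$outcomes$review_id == "R1"] <- "Pain at 6 weeks"
  anom <- detect_structural_anomalies(db)
  expect_equal(sum(anom$type == "duplicate_outcome_name"), 2)

  db2 <- tiny_db()
  db2$outcomes$name[1] <- NA
  anom2 <- detect_structural_anomalies(db2)
  expect_equal(sum(anom2$type == "missing_outcome_name"), 1)

  db3 <- tiny_db()
  db3$studies$mean_1[1] <- 5  # continuous field on a dichotomous plot
  anom3 <- detect_structural_anomalies(db3)
  expect_equal(sum(anom3$type == "payload_type_conflict"), 1)
  expect_equal(db3$studies$mean_1[1], 5)  # data untouched
})

test_that("curation report serialises to ledger CSV and text summary", {
  gen <- generate_database(test_config(n_reviews = 20, seed = 3))
  report <- curate(gen$db)
  csv <- withr::local_tempfile(fileext = ".csv")
  txt <- withr::local_tempfile(fileext = ".txt")
  write_curation_report(report, csv, txt)
  led <- read.csv(csv)
  expect_setequal(unique(led$ledger), c("review", "meta_analysis", "study"))
  expect_true(any(grepl("remaining", readLines(txt))))
})
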