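vocabs <- default_vocabularies()

test_that("shipped vocabularies have the fixed sizes and structure", {
  expect_length(vocabs$specialty, 11)
  expect_length(vocabs$intervention$active, 15)
  expect_length(vocabs$intervention$control, 2)
  expect_length(vocabs$outcome$categories, 23)
  expect_setequal(vocabs$outcome$priority_order, vocabs$outcome$categories)
  # 23 -> 11 collapse is total and surjective
  expect_setequal(names(vocabs$outcome_group11), vocabs$outcome$categories)
  expect_length(unique(unname(vocabs$outcome_group11)), 11)
  # 4 data types -> 3 groups
  expect_length(unique(unname(vocabs$data_type_group)), 3)
  expect_equal(unname(vocabs$data_type_group[c("generic", "oe_variance")]),
               c("Mixed", "Mixed"))
})

test_that("vocabulary constructors reject malformed inputs", {
  expect_error(specialty_vocab(letters[1:10]), "11")
  expect_error(outcome_vocab(as.character(1:23), as.character(1:22)),
               "permutation")
  expect_error(intervention_vocab(as.character(1:14)), "15")
})

test_that("priority resolution picks the highest-listed candidate", {
  ov <- vocabs$outcome
  expect_equal(resolve_outcome_category("Pain", ov), "Pain")
  # Adverse events sits above Pain in the shipped priority order
  expect_equal(resolve_outcome_category(c("Pain", "Adverse events"), ov),
               "Adverse events")
  # invariant to candidate ordering
  expect_equal(resolve_outcome_category(c("Adverse events", "Pain"), ov),
               resolve_outcome_category(c("Pain", "Adverse events"), ov))
  expect_equal(
    resolve_outcome_category(c("Pain", "All-cause mortality", "Other"), ov),
    "All-cause mortality")
  expect_error(resolve_outcome_category(character(0), ov), "empty")
  expect_error(resolve_outcome_category("Dermatology", ov), "unknown")
})

test_that("comparison classification fills the cross-tab cells", {
  iv <- vocabs$intervention
  c1 <- classify_comparison("Pharmacological", "Placebo", iv)
  expect_equal(c1$comparator_kind, "Placebo")
  expect_equal(c1$collapsed5, "Pharm vs Control/Placebo")

  c2 <- classify_comparison("Surgical", "Surgical", iv)
  expect_equal(c2$comparator_kind, "same-category non-pharm")
  expect_equal(c2$collapsed5, "Non-Pharm vs Non-Pharm")

  c3 <- classify_comparison("Pharmacological", "Pharmacological", iv)
  expect_equal(c3$comparator_kind, "Pharmacological")
  expect_equal(c3$collapsed5, "Pharm vs Pharm")

  expect_equal(classify_comparison("Pharmacological", "Surgical", iv)$comparator_kind,
               "different-category non-pharm")
  expect_equal(classify_comparison("Pharmacological", "Surgical", iv)$collapsed5,
               "Pharm vs Non-Pharm")
  expect_equal(classify_comparison("Surgical", "Pharmacological", iv)$collapsed5,
               "Pharm vs Non-Pharm")
  expect_equal(classify_comparison("Surgical", "Control", iv)$collapsed5,
               "Non-Pharm vs Control/Placebo")
  expect_equal(classify_comparison("Surgical", "Behavioural", iv)$collapsed5,
               "Non-Pharm vs Non-Pharm")
  expect_error(classify_comparison("Homeopathy", "Control", iv), "unknown")
  expect_error(classify_comparison("Pharmacological", "Sham", iv), "unknown")
})

test_that("every (active, comparator) pair maps to exactly one collapsed group", {
  iv <- vocabs$intervention
  for (active in iv$active) {
    for (comparator in c(iv$active, iv$control)) {
      cls <- classify_comparison(active, comparator, iv)
      expect_length(cls$collapsed5, 1)
      expect_true(cls$collapsed5 %in% srcensus:::COLLAPSED5)
      # the structurally excluded cell is unreachable
      if (active == iv$pharmacological) {
        expect_false(cls$comparator_kind == "same-category non-pharm")
      }
    }
  }
})

test_that("outcome collapse maps categories onto the summary groups", {
  map <- vocabs$outcome_group11
  expect_equal(collapse_outcome_group("All-cause mortality", map),
               "All-cause mortality")
  expect_equal(collapse_outcome_group("Hospital stay/process measures", map),
               "Resource use/hospital stay/process")
  expect_equal(collapse_outcome_group("Resource use", map),
               "Resource use/hospital stay/process")
  expect_equal(
    collapse_outcome_group("Cause-specific mortality", map),
    "Cause-specific mortality/major morbidity event/composite (mortality or morbidity)")
  expect_error(collapse_outcome_group("Dermatology", map), "unknown")
})

test_that("label validation reports path-qualified violations", {
  expect_equal(nrow(validate_labels(tiny_db(), vocabs)), 0)

  db <- tiny_db()
  db$reviews$specialty_label[1] <- "Dermatology"
  v <- validate_labels(db, vocabs)
  expect_equal(nrow(v), 1)
  expect_equal(v$path, "R1")

  db2 <- tiny_db()
  db2$outcomes$outcome_category_label[2] <- NA
  v2 <- validate_labels(db2, vocabs)
  expect_equal(nrow(v2), 1)
  expect_match(v2$message, "missing outcome category")
  expect_equal(v2$path, "R1/C1/O2")
})
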