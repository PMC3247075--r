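# Hand-built fixtures and independent oracles shared across the suite.

# one review, one comparison, one dichotomous plot with the given study
# rows (list of c(events_1, total_1, events_2, total_2))
dich_plot_db <- function(rows, study_ids = NULL, subgroups = NULL,
                         review_id = "R1", status = "full") {
  n <- length(rows)
  if (is.null(study_ids)) study_ids <- sprintf("Study %d", seq_len(n))
  if (is.null(subgroups)) subgroups <- rep("All studies", n)
  m <- do.call(rbind, rows)
  sr_database(
    reviews = data.frame(review_id = review_id, title = "t", review_group = "g",
                         status = status, is_methodology_group = FALSE,
                         specialty_label = "Cancer"),
    comparisons = data.frame(review_id = review_id, comparison_id = "C1",
                             name = "a vs b",
                             active_intervention_label = "Pharmacological",
                             comparator_label = "Placebo"),
    outcomes = data.frame(review_id = review_id, comparison_id = "C1",
                          outcome_id = "O1", name = "death",
                          data_type = "dichotomous", totals_displayed = TRUE,
                          outcome_category_label = "All-cause mortality"),
    studies = data.frame(review_id = review_id, comparison_id = "C1",
                         outcome_id = "O1", subgroup = subgroups,
                         study_id = study_ids,
                         events_1 = m[, 1], total_1 = m[, 2],
                         events_2 = m[, 3], total_2 = m[, 4])
  )
}

# a small clean multi-review database exercising all four data types
tiny_db <- function() {
  reviews <- data.frame(
    review_id = c("R1", "R2"),
    title = c("one", "two"), review_group = c("g1", "g2"),
    status = "full", is_methodology_group = FALSE,
    specialty_label = c("Cancer", "Urogenital")
  )
  comparisons <- data.frame(
    review_id = c("R1", "R2"), comparison_id = "C1",
    name = "a vs b",
    active_intervention_label = c("Pharmacological", "Surgical"),
    comparator_label = c("Placebo", "Surgical")
  )
  outcomes <- data.frame(
    review_id = c("R1", "R1", "R2", "R2"),
    comparison_id = "C1",
    outcome_id = c("O1", "O2", "O1", "O2"),
    name = c("death", "qol", "stay", "events"),
    data_type = c("dichotomous", "continuous", "generic", "oe_variance"),
    totals_displayed = TRUE,
    outcome_category_label = c("All-cause mortality",
                               "Quality of life/functioning",
                               "Hospital stay/process measures",
                               "Major morbidity event")
  )
  base <- expand.grid(stringsAsFactors = FALSE,
                      study_id = c("Smith 2001", "Jones 2002", "Chen 2003"),
                      outcome_id = c("O1", "O2"))
  st <- rbind(
    data.frame(review_id = "R1", comparison_id = "C1",
               outcome_id = base$outcome_id, subgroup = "All studies",
               study_id = base$study_id),
    data.frame(review_id = "R2", comparison_id = "C1",
               outcome_id = base$outcome_id, subgroup = "All studies",
               study_id = base$study_id)
  )
  st[PAYLOAD_COLS_T()] <- NA_real_
  dich <- st$review_id == "R1" & st$outcome_id == "O1"
  st[dich, c("events_1", "total_1", "events_2", "total_2")] <-
    rep(c(3, 50, 5, 48), each = 3)
  cont <- st$review_id == "R1" & st$outcome_id == "O2"
  st[cont, c("n_1", "mean_1", "sd_1", "n_2", "mean_2", "sd_2")] <-
    rep(c(30, 1.2, 0.4, 32, 1.0, 0.5), each = 3)
  gen <- st$review_id == "R2" & st$outcome_id == "O1"
  st[gen, c("estimate", "standard_error", "total_n")] <-
    rep(c(0.3, 0.1, 120), each = 3)
  oe <- st$review_id == "R2" & st$outcome_id == "O2"
  st[oe, c("o_minus_e", "variance", "total_n")] <- rep(c(-2.1, 4, 80), each = 3)
  sr_database(reviews, comparisons, outcomes, st)
}

PAYLOAD_COLS_T <- function() {
  c("events_1", "total_1", "events_2", "total_2",
    "n_1", "mean_1", "sd_1", "n_2", "mean_2", "sd_2",
    "estimate", "standard_error", "o_minus_e", "variance", "total_n")
}

# Independent exact rank-sum oracle: enumerates group assignments of the
# pooled values and computes U by direct pairwise comparison (a different
# route than the implementation's rank-sum formula).
oracle_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  N <- length(pooled)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  U_obs <- u_of(x, y)
  centre <- n1 * (N - n1) / 2
  combs <- combn(N, n1)
  Us <- apply(combs, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  mean(abs(Us - centre) >= abs(U_obs - centre) - 1e-9)
}

# generator config sized for fast tests, no review-level contamination
test_config <- function(n_reviews, seed, ...) {
  default_config(n_reviews = n_reviews, seed = seed,
                 protocol_rate = 0, withdrawn_rate = 0, methodology_rate = 0,
                 ...)
}
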