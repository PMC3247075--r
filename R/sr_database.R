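# Core data model: a review collection held in relational form.
#
# A systematic-review database is a four-level hierarchy
#   review -> pair-wise comparison -> outcome (one forest plot) ->
#   subgroup -> study entry
# stored as four linked data frames plus a free-text issue label. Row order
# is document order; within a forest plot it is the order studies appear
# down the plot, which the deduplication rule depends on.

#' Study payload columns, by data type
#'
#' Each study entry carries exactly one of four payloads, mirrored in a
#' fixed set of wide numeric columns (`NA` where not applicable):
#' \describe{
#'   \item{dichotomous}{`events_1`, `total_1`, `events_2`, `total_2` --
#'     event counts and arm sizes.}
#'   \item{continuous}{`n_1`, `mean_1`, `sd_1`, `n_2`, `mean_2`, `sd_2` --
#'     per-arm sample size, mean and standard deviation.}
#'   \item{generic}{`estimate`, `standard_error`, optional `total_n` --
#'     an effect estimate with its standard error.}
#'   \item{oe_variance}{`o_minus_e`, `variance`, optional `total_n` --
#'     observed-minus-expected events with variance, typically from
#'     time-to-event analyses.}
#' }
#' @name payload-columns
#' @keywords internal
NULL

empty_reviews <- function() {
  data.frame(
    review_id = character(0), title = character(0),
    review_group = character(0), status = character(0),
    is_methodology_group = logical(0), specialty_label = character(0),
    stringsAsFactors = FALSE
  )
}

empty_comparisons <- function() {
  data.frame(
    review_id = character(0), comparison_id = character(0),
    name = character(0), active_intervention_label = character(0),
    comparator_label = character(0), stringsAsFactors = FALSE
  )
}

empty_outcomes <- function() {
  data.frame(
    review_id = character(0), comparison_id = character(0),
    outcome_id = character(0), name = character(0), data_type = character(0),
    totals_displayed = logical(0), outcome_category_label = character(0),
    stringsAsFactors = FALSE
  )
}

empty_studies <- function() {
  out <- data.frame(
    review_id = character(0), comparison_id = character(0),
    outcome_id = character(0), subgroup = character(0),
    study_id = character(0), stringsAsFactors = FALSE
  )
  for (col in PAYLOAD_COLS) out[[col]] <- numeric(0)
  out
}

coerce_frame <- function(x, template, what) {
  if (is.null(x)) return(template)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing <- setdiff(names(template), names(x))
  for (col in missing) {
    x[[col]] <- if (is.character(template[[col]])) NA_character_
                else if (is.logical(template[[col]])) NA
                else NA_real_
  }
  extra <- setdiff(names(x), names(template))
  if (length(extra)) {
    stop(sprintf("unknown column(s) in %s: %s", what,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  x <- x[, names(template), drop = FALSE]
  for (col in names(template)) {
    if (is.character(template[[col]])) x[[col]] <- as.character(x[[col]])
    if (is.logical(template[[col]]))   x[[col]] <- as.logical(x[[col]])
    if (is.numeric(template[[col]]))   x[[col]] <- as.numeric(x[[col]])
  }
  rownames(x) <- NULL
  x
}

#' Construct a systematic-review database
#'
#' Builds the package's central container from four relational tables. The
#' object mirrors the 'Data and analyses' hierarchy of a review collection:
#' reviews hold pair-wise comparisons, comparisons hold outcomes (each
#' outcome is one forest plot and one candidate meta-analysis), and each
#' forest plot holds study entries grouped into possibly overlapping
#' subgroups.
#'
#' Identifiers are free-form strings, matched exactly after trimming
#' leading/trailing whitespace (case-sensitive). Row order is document
#' order and is preserved by all operations.
#'
#' @param reviews data frame with columns `review_id`, `title`,
#'   `review_group`, `status` (`"full"`, `"protocol"` or `"withdrawn"`),
#'   `is_methodology_group` (logical), `specialty_label` (may be `NA`).
#' @param comparisons data frame with columns `review_id`, `comparison_id`,
#'   `name`, `active_intervention_label`, `comparator_label`.
#' @param outcomes data frame with columns `review_id`, `comparison_id`,
#'   `outcome_id`, `name`, `data_type` (one of `"dichotomous"`,
#'   `"continuous"`, `"generic"`, `"oe_variance"`), `totals_displayed`
#'   (logical), `outcome_category_label`.
#' @param studies data frame with columns `review_id`, `comparison_id`,
#'   `outcome_id`, `subgroup`, `study_id` and the wide payload columns
#'   (see [payload-columns]). One row per study entry, in forest-plot
#'   document order.
#' @param issue_label free-text label for the database issue.
#' @param validate if `TRUE` (default), run [validate_sr_database()].
#'
#' @return An object of class `sr_database`.
#' @seealso [load_database()], [validate_sr_database()], [sample_size()]
#' @export
#' @examples
#' db <- sr_database(
#'   reviews = data.frame(review_id = "R1", title = "Example", review_group = "G",
#'                        status = "full", is_methodology_group = FALSE,
#'                        specialty_label = "Cancer"),
#'   comparisons = data.frame(review_id = "R1", comparison_id = "C1",
#'                            name = "A vs B",
#'                            active_intervention_label = "Pharmacological",
#'                            comparator_label = "Placebo"),
#'   outcomes = data.frame(review_id = "R1", comparison_id = "C1",
#'                         outcome_id = "O1", name = "Mortality",
#'                         data_type = "dichotomous", totals_displayed = TRUE,
#'                         outcome_category_label = "All-cause mortality"),
#'   studies = data.frame(review_id = "R1", comparison_id = "C1",
#'                        outcome_id = "O1", subgroup = "All studies",
#'                        study_id = c("Smith 2001", "Jones 2003"),
#'                        events_1 = c(3, 5), total_1 = c(50, 40),
#'                        events_2 = c(5, 9), total_2 = c(48, 44))
#' )
#' n_meta_analyses(db)
sr_database <- function(reviews = NULL, comparisons = NULL, outcomes = NULL,
                        studies = NULL, issue_label = "unlabelled",
                        validate = TRUE) {
  db <- structure(
    list(
      issue_label = as.character(issue_label)[1],
      reviews     = coerce_frame(reviews, empty_reviews(), "reviews"),
      comparisons = coerce_frame(comparisons, empty_comparisons(), "comparisons"),
      outcomes    = coerce_frame(outcomes, empty_outcomes(), "outcomes"),
      studies     = coerce_frame(studies, empty_studies(), "studies")
    ),
    class = "sr_database"
  )
  # identifier hygiene: exact matching after whitespace trim
  db$reviews$review_id <- trimws(db$reviews$review_id)
  for (tab in c("comparisons", "outcomes", "studies")) {
    db[[tab]]$review_id <- trimws(db[[tab]]$review_id)
    db[[tab]]$comparison_id <- trimws(db[[tab]]$comparison_id)
  }
  for (tab in c("outcomes", "studies")) db[[tab]]$outcome_id <- trimws(db[[tab]]$outcome_id)
  db$studies$study_id <- trimws(db$studies$study_id)
  if (validate) validate_sr_database(db)
  db
}

#' @export
print.sr_database <- function(x, ...) {
  cat(sprintf("<sr_database> issue: %s\n", x$issue_label))
  cat(sprintf("  reviews:      %d\n", nrow(x$reviews)))
  cat(sprintf("  comparisons:  %d\n", nrow(x$comparisons)))
  cat(sprintf("  forest plots: %d\n", nrow(x$outcomes)))
  cat(sprintf("  study rows:   %d\n", nrow(x$studies)))
  invisible(x)
}

is_sr_database <- function(x) inherits(x, "sr_database")

key3 <- function(df) paste(df$review_id, df$comparison_id, df$outcome_id, sep = "\r")
key2 <- function(df) paste(df$review_id, df$comparison_id, sep = "\r")

#' Validate a systematic-review database
#'
#' Checks referential integrity and the domain invariants of every record:
#' identifier uniqueness at each level, non-empty study identifiers,
#' non-negative counts, `events <= total` per arm, non-negative standard
#' deviations / standard errors / variances, and that each study entry's
#' payload columns are exactly those of its forest plot's declared data
#' type (required fields present, foreign fields absent).
#'
#' @param db an [sr_database()].
#' @return `db`, invisibly, if valid; otherwise an error whose message
#'   lists the path into the hierarchy of each offending record.
#' @export
validate_sr_database <- function(db) {
  stopifnot(is_sr_database(db))
  problems <- character(0)
  note <- function(fmt, ...) problems <<- c(problems, sprintf(fmt, ...))

  rv <- db$reviews
  dup <- rv$review_id[duplicated(rv$review_id)]
  if (length(dup)) note("duplicate review_id: %s", paste(unique(dup), collapse = ", "))
  bad <- !rv$status %in% REVIEW_STATUSES
  if (any(bad)) note("review %s: invalid status '%s'",
                     rv$review_id[bad][1], rv$status[bad][1])
  if (anyNA(rv$is_methodology_group))
    note("review %s: is_methodology_group missing",
         rv$review_id[is.na(rv$is_methodology_group)][1])

  cp <- db$comparisons
  orphan <- !cp$review_id %in% rv$review_id
  if (any(orphan)) note("comparison %s/%s: unknown review_id",
                        cp$review_id[orphan][1], cp$comparison_id[orphan][1])
  dup <- duplicated(key2(cp))
  if (any(dup)) note("review %s: duplicate comparison_id '%s'",
                     cp$review_id[dup][1], cp$comparison_id[dup][1])

  oc <- db$outcomes
  orphan <- !key2(oc) %in% key2(cp)
  if (any(orphan)) note("outcome %s/%s/%s: unknown comparison",
                        oc$review_id[orphan][1], oc$comparison_id[orphan][1],
                        oc$outcome_id[orphan][1])
  dup <- duplicated(key3(oc))
  if (any(dup)) note("comparison %s/%s: duplicate outcome_id '%s'",
                     oc$review_id[dup][1], oc$comparison_id[dup][1],
                     oc$outcome_id[dup][1])
  bad <- !oc$data_type %in% DATA_TYPES
  if (any(bad)) note("outcome %s/%s/%s: invalid data_type '%s'",
                     oc$review_id[bad][1], oc$comparison_id[bad][1],
                     oc$outcome_id[bad][1], oc$data_type[bad][1])

  st <- db$studies
  orphan <- !key3(st) %in% key3(oc)
  if (any(orphan)) note("study %s/%s/%s/'%s': unknown forest plot",
                        st$review_id[orphan][1], st$comparison_id[orphan][1],
                        st$outcome_id[orphan][1], st$study_id[orphan][1])
  if (nrow(st)) {
    if (any(is.na(st$study_id) | st$study_id == ""))
      note("study with empty study_id under plot %s",
           key_path(st[is.na(st$study_id) | st$study_id == "", ][1, ]))
    if (anyNA(st$subgroup) || any(st$subgroup == ""))
      note("study '%s' with empty subgroup name",
           st$study_id[is.na(st$subgroup) | st$subgroup == ""][1])

    dtype <- oc$data_type[match(key3(st), key3(oc))]

    chk <- function(cond, fmt) {
      bad <- which(!is.na(cond) & cond)
      if (length(bad))
        note(paste0(fmt, " (study '%s' in plot %s)"),
             st$study_id[bad[1]], key_path(st[bad[1], ]))
    }
    chk(st$events_1 < 0 | st$total_1 < 0 | st$events_2 < 0 | st$total_2 < 0,
        "negative count in dichotomous payload")
    chk(st$events_1 > st$total_1 | st$events_2 > st$total_2,
        "events exceed arm total")
    chk(st$n_1 < 0 | st$n_2 < 0, "negative arm size in continuous payload")
    chk(st$sd_1 < 0 | st$sd_2 < 0, "negative standard deviation")
    chk(st$standard_error < 0, "negative standard error")
    chk(st$variance < 0, "negative variance")
    chk(st$total_n < 0, "negative total_n")

    req_missing <- rep(FALSE, nrow(st))
    for (dt in DATA_TYPES) {
      idx <- which(!is.na(dtype) & dtype == dt)
      for (col in REQUIRED_PAYLOAD[[dt]])
        req_missing[idx] <- req_missing[idx] | is.na(st[[col]][idx])
    }
    if (any(req_missing))
      note("required payload fields missing for data_type '%s' (study '%s' in plot %s)",
           dtype[which(req_missing)[1]], st$study_id[which(req_missing)[1]],
           key_path(st[which(req_missing)[1], ]))
  }

  if (length(problems)) {
    stop("invalid sr_database:\n  ",
         paste(utils::head(problems, 10), collapse = "\n  "), call. = FALSE)
  }
  invisible(db)
}

key_path <- function(row) {
  paste(row$review_id, row$comparison_id, row$outcome_id, sep = "/")
}

# TRUE where a study row's non-NA payload columns are not exactly the
# declared data type's required set (plus its optional extras)
payload_mismatch <- function(st, dtype) {
  mism <- logical(nrow(st))
  for (dt in DATA_TYPES) {
    idx <- which(!is.na(dtype) & dtype == dt)
    if (!length(idx)) next
    req <- REQUIRED_PAYLOAD[[dt]]
    allowed <- c(req, OPTIONAL_PAYLOAD[[dt]])
    forbidden <- setdiff(PAYLOAD_COLS, allowed)
    m <- rep(FALSE, length(idx))
    for (col in req)       m <- m | is.na(st[[col]][idx])
    for (col in forbidden) m <- m | !is.na(st[[col]][idx])
    mism[idx] <- m
  }
  mism
}

#' Participant sample size of study entries
#'
#' For dichotomous and continuous payloads the sample size is the sum of
#' the two arm sizes; for generic and O-E/variance payloads it is the
#' optional `total_n` field when recorded and missing (`NA`) otherwise.
#'
#' @param x an [sr_database()], or a studies data frame that carries a
#'   `data_type` column alongside the payload columns.
#' @return Numeric vector, one element per study row, `NA` where the
#'   sample size is not recorded.
#' @export
#' @examples
#' df <- data.frame(data_type = "dichotomous", study_id = "s",
#'                  events_1 = 3, total_1 = 50, events_2 = 5, total_2 = 48)
#' sample_size(df)  # 98
sample_size <- function(x) {
  if (is_sr_database(x)) {
    st <- x$studies
    st$data_type <- x$outcomes$data_type[match(key3(st), key3(x$outcomes))]
  } else {
    st <- x
    if (is.null(st$data_type)) stop("need a data_type column", call. = FALSE)
  }
  if (!nrow(st)) return(numeric(0))
  for (col in PAYLOAD_COLS) if (is.null(st[[col]])) st[[col]] <- NA_real_
  out <- rep(NA_real_, nrow(st))
  i <- st$data_type == "dichotomous"
  out[i] <- st$total_1[i] + st$total_2[i]
  i <- st$data_type == "continuous"
  out[i] <- st$n_1[i] + st$n_2[i]
  i <- st$data_type %in% c("generic", "oe_variance")
  out[i] <- st$total_n[i]
  out
}

#' Database size accessors
#'
#' `n_reviews()`, `n_meta_analyses()` and `n_study_rows()` count reviews,
#' forest plots and study entries.
#'
#' @param db an [sr_database()].
#' @return Integer count.
#' @export
n_reviews <- function(db) nrow(db$reviews)

#' @rdname n_reviews
#' @export
n_meta_analyses <- function(db) nrow(db$outcomes)

#' @rdname n_reviews
#' @export
n_study_rows <- function(db) nrow(db$studies)

#' Flat per-plot and per-study views
#'
#' `plot_table()` returns one row per forest plot with its review-level
#' specialty, comparison-level intervention labels, declared data type,
#' outcome category and number of study rows. `study_table()` returns one
#' row per study entry with the same labels, the plot's data type, the
#' entry's position within the plot (document order) and its participant
#' [sample_size()]. These flat views feed the census engine.
#'
#' @param db an [sr_database()].
#' @return A data frame.
#' @export
plot_table <- function(db) {
  oc <- db$outcomes
  cp <- db$comparisons
  rv <- db$reviews
  oc$specialty_label <- rv$specialty_label[match(oc$review_id, rv$review_id)]
  m <- match(key2(oc), key2(cp))
  oc$active_intervention_label <- cp$active_intervention_label[m]
  oc$comparator_label <- cp$comparator_label[m]
  tab <- table(factor(key3(db$studies), levels = key3(oc)))
  oc$n_studies <- as.integer(tab)
  rownames(oc) <- NULL
  oc
}

#' @rdname plot_table
#' @export
study_table <- function(db) {
  st <- db$studies
  oc <- db$outcomes
  m <- match(key3(st), key3(oc))
  st$data_type <- oc$data_type[m]
  st$outcome_category_label <- oc$outcome_category_label[m]
  rv <- db$reviews
  st$specialty_label <- rv$specialty_label[match(st$review_id, rv$review_id)]
  cp <- db$comparisons
  m2 <- match(key2(st), key2(cp))
  st$active_intervention_label <- cp$active_intervention_label[m2]
  st$comparator_label <- cp$comparator_label[m2]
  st$position <- plot_positions(st)
  st$sample_size <- sample_size(st)
  rownames(st) <- NULL
  st
}

# position of each study row within its forest plot, in document order
plot_positions <- function(st) {
  if (!nrow(st)) return(integer(0))
  k <- key3(st)
  stats::ave(seq_along(k), k, FUN = seq_along)
}

#' Extract one forest plot
#'
#' @param db an [sr_database()].
#' @param review_id,comparison_id,outcome_id identifiers of the plot.
#' @return A list with elements `outcome` (one-row data frame) and
#'   `studies` (the plot's study rows in document order, with a
#'   `data_type` column attached).
#' @export
get_plot <- function(db, review_id, comparison_id, outcome_id) {
  k <- paste(review_id, comparison_id, outcome_id, sep = "\r")
  oc <- db$outcomes[key3(db$outcomes) == k, , drop = FALSE]
  if (!nrow(oc)) stop("no such forest plot: ",
                      paste(review_id, comparison_id, outcome_id, sep = "/"),
                      call. = FALSE)
  st <- db$studies[key3(db$studies) == k, , drop = FALSE]
  st$data_type <- oc$data_type[1]
  rownames(st) <- NULL
  rownames(oc) <- NULL
  list(outcome = oc, studies = st)
}
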