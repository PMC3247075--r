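# Eligibility and cleaning pipeline.
#
# Review-level exclusions (protocols, withdrawn reviews, the methodology
# group), removal of phantom study records left behind by legacy
# forest-plot software, within-plot deduplication of studies repeated
# across overlapping subgroups, and the rule that a forest plot must hold
# at least two distinct genuine studies to count as a meta-analysis.
# Every stage is accounted for in a conservation-checked flow ledger.

#' Flow ledger
#'
#' A stage-by-stage record of how many records entered a cleaning stage
#' and how many were excluded there, with the exclusion reason. The
#' records entering stage k+1 always equal the records entering stage k
#' minus that stage's exclusions.
#'
#' @param stages character vector of stage names.
#' @param records_in integer vector, records entering each stage.
#' @param excluded integer vector, records excluded at each stage.
#' @param reason character vector of exclusion reasons.
#' @return A data frame of class `flow_ledger` with those four columns.
#' @export
flow_ledger <- function(stages = character(0), records_in = integer(0),
                        excluded = integer(0), reason = stages) {
  led <- data.frame(
    stage = as.character(stages),
    records_in = as.integer(records_in),
    excluded = as.integer(excluded),
    reason = as.character(reason),
    stringsAsFactors = FALSE
  )
  class(led) <- c("flow_ledger", "data.frame")
  validate_flow_ledger(led)
  led
}

validate_flow_ledger <- function(led) {
  if (any(led$records_in < 0) || any(led$excluded < 0))
    stop("flow ledger counts must be non-negative", call. = FALSE)
  if (any(led$excluded > led$records_in))
    stop("flow ledger excludes more records than entered a stage", call. = FALSE)
  if (nrow(led) > 1) {
    carried <- led$records_in[-nrow(led)] - led$excluded[-nrow(led)]
    if (any(carried != led$records_in[-1]))
      stop("flow ledger violates conservation between stages", call. = FALSE)
  }
  invisible(led)
}

#' @export
print.flow_ledger <- function(x, ...) {
  cat("<flow_ledger>\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

ledger_remaining <- function(led) {
  if (!nrow(led)) return(NA_integer_)
  led$records_in[nrow(led)] - led$excluded[nrow(led)]
}

#' Curation options
#'
#' Tuning knobs for the cleaning rules where the field's conventions
#' leave room:
#' \describe{
#'   \item{generic_phantoms}{treat a generic payload with estimate 0 and
#'     standard error 0 as a phantom record (default `TRUE`). The classic
#'     zero-patterns are defined for dichotomous, continuous and
#'     O-E/variance data; this extends the same logic to generic rows and
#'     can be switched off.}
#'   \item{continuous_phantom_allocation}{`"one_per_arm"` (default)
#'     requires exactly one participant per arm for the continuous
#'     phantom pattern; `"any_split"` accepts any arm allocation whose
#'     total is 2.}
#' }
#'
#' @param generic_phantoms logical.
#' @param continuous_phantom_allocation `"one_per_arm"` or `"any_split"`.
#' @return A list of class `curation_options`.
#' @export
curation_options <- function(generic_phantoms = TRUE,
                             continuous_phantom_allocation =
                               c("one_per_arm", "any_split")) {
  structure(
    list(
      generic_phantoms = isTRUE(generic_phantoms),
      continuous_phantom_allocation = match.arg(continuous_phantom_allocation)
    ),
    class = "curation_options"
  )
}

#' Review-level eligibility filter
#'
#' Drops protocols, withdrawn reviews and reviews from the methodology
#' group, in that order, recording each exclusion reason as its own
#' ledger stage. Children of dropped reviews are dropped with them.
#'
#' @param db an [sr_database()].
#' @return A list with elements `db` (the filtered database) and `ledger`
#'   (a review-level [flow_ledger()]).
#' @export
filter_reviews <- function(db) {
  stopifnot(is_sr_database(db))
  rv <- db$reviews
  stages <- list(
    c(stage = "protocol", reason = "protocol, not a full review"),
    c(stage = "withdrawn", reason = "review marked as withdrawn"),
    c(stage = "methodology group", reason = "methodology review group")
  )
  drop_rule <- list(
    protocol = function(r) r$status == "protocol",
    withdrawn = function(r) r$status == "withdrawn",
    `methodology group` = function(r) r$is_methodology_group
  )
  records_in <- integer(0); excluded <- integer(0)
  for (s in stages) {
    n_in <- nrow(rv)
    drop <- drop_rule[[s[["stage"]]]](rv)
    records_in <- c(records_in, n_in)
    excluded <- c(excluded, sum(drop))
    rv <- rv[!drop, , drop = FALSE]
  }
  led <- flow_ledger(vapply(stages, `[[`, "", "stage"), records_in, excluded,
                     vapply(stages, `[[`, "", "reason"))
  list(db = subset_reviews(db, rv$review_id), ledger = led)
}

subset_reviews <- function(db, keep_ids) {
  db$reviews <- db$reviews[db$reviews$review_id %in% keep_ids, , drop = FALSE]
  db$comparisons <- db$comparisons[db$comparisons$review_id %in% keep_ids, , drop = FALSE]
  db$outcomes <- db$outcomes[db$outcomes$review_id %in% keep_ids, , drop = FALSE]
  db$studies <- db$studies[db$studies$review_id %in% keep_ids, , drop = FALSE]
  for (tab in c("reviews", "comparisons", "outcomes", "studies"))
    rownames(db[[tab]]) <- NULL
  db
}

#' Phantom study records
#'
#' Legacy forest-plot software stored a row for every study listed in a
#' plot even when the study contributed no data to that meta-analysis,
#' producing recognisable zero-patterns at an apparent sample size of 2:
#' dichotomous rows with 0 events out of 1 in each arm, continuous rows
#' with total sample size 2 and means and standard deviations of 0 in
#' each arm, and O-E/variance rows with both quantities 0. Such rows are
#' almost never genuine data. Size-2 rows with any other data pattern are
#' not phantoms.
#'
#' `is_phantom_study()` tests one study entry; `phantom_flags()` is the
#' vectorised version over a studies table (as from [study_table()]).
#'
#' @param entry a one-row data frame (or list) with the payload fields
#'   and a `data_type` field.
#' @param options a [curation_options()] object.
#' @return A logical (vector, for `phantom_flags()`).
#' @export
#' @examples
#' is_phantom_study(data.frame(data_type = "dichotomous", study_id = "s",
#'                             events_1 = 0, total_1 = 1,
#'                             events_2 = 0, total_2 = 1))  # TRUE
is_phantom_study <- function(entry, options = curation_options()) {
  entry <- as.data.frame(as.list(entry), stringsAsFactors = FALSE)
  phantom_flags(entry, options)
}

#' @rdname is_phantom_study
#' @param st a studies data frame carrying `data_type` and payload columns.
#' @export
phantom_flags <- function(st, options = curation_options()) {
  if (!nrow(st)) return(logical(0))
  for (col in PAYLOAD_COLS) if (is.null(st[[col]])) st[[col]] <- NA_real_
  eq0 <- function(x) !is.na(x) & x == 0
  eq <- function(x, v) !is.na(x) & x == v
  out <- rep(FALSE, nrow(st))

  i <- st$data_type == "dichotomous"
  out[i] <- (eq(st$total_1, 1) & eq(st$total_2, 1) &
             eq0(st$events_1) & eq0(st$events_2))[i]

  i <- st$data_type == "continuous"
  alloc <- if (options$continuous_phantom_allocation == "one_per_arm") {
    eq(st$n_1, 1) & eq(st$n_2, 1)
  } else {
    eq(st$n_1 + st$n_2, 2)
  }
  out[i] <- (alloc & eq0(st$mean_1) & eq0(st$mean_2) &
             eq0(st$sd_1) & eq0(st$sd_2))[i]

  i <- st$data_type == "oe_variance"
  out[i] <- (eq0(st$o_minus_e) & eq0(st$variance))[i]

  if (options$generic_phantoms) {
    i <- st$data_type == "generic"
    out[i] <- (eq0(st$estimate) & eq0(st$standard_error))[i]
  }
  out
}

#' Deduplicate one forest plot
#'
#' When subgroups within a forest plot are not mutually exclusive, the
#' same study can appear more than once in the plot. Only the first
#' occurrence of each distinct `study_id` (document order, across
#' subgroups) is kept; later occurrences are dropped. Identity is exact
#' string match after whitespace trimming, so labels such as
#' `"Smith 2001a"` and `"Smith 2001b"` are distinct and both kept.
#'
#' @param plot a plot as returned by [get_plot()], or a studies data
#'   frame for a single plot in document order.
#' @return A list with the deduplicated `plot` (same shape as the input)
#'   and `removed`, the number of rows dropped.
#' @export
deduplicate_plot <- function(plot) {
  st <- if (is.data.frame(plot)) plot else plot$studies
  dup <- duplicated(st$study_id)
  kept <- st[!dup, , drop = FALSE]
  rownames(kept) <- NULL
  out <- if (is.data.frame(plot)) kept else {
    plot$studies <- kept
    plot
  }
  list(plot = out, removed = sum(dup))
}

# vectorised across plots: TRUE for every later occurrence of a study_id
# within its forest plot
duplicate_flags <- function(st) {
  if (!nrow(st)) return(logical(0))
  duplicated(paste(key3(st), st$study_id, sep = "\r"))
}

#' Select eligible meta-analyses
#'
#' Applies the study- and plot-level cleaning stages to a review-filtered
#' database, in order: phantom-record removal, within-plot deduplication,
#' removal of forest plots left with fewer than two distinct studies, and
#' removal of comparisons and reviews left with no eligible plot. Three
#' conservation-checked ledgers (reviews, meta-analyses, studies) record
#' every stage.
#'
#' @param db an [sr_database()] that has passed [filter_reviews()].
#' @param options a [curation_options()] object.
#' @return A `curation_report`: a list with `review_ledger`,
#'   `meta_analysis_ledger`, `study_ledger`, the `curated` database, and
#'   `removed`, a list of data frames keying the study rows removed as
#'   phantoms, as duplicates, and with underfilled plots (columns
#'   `review_id`, `comparison_id`, `outcome_id`, `subgroup`, `study_id`,
#'   `position`).
#' @export
select_eligible_meta_analyses <- function(db, options = curation_options()) {
  stopifnot(is_sr_database(db))
  st <- db$studies
  oc <- db$outcomes
  st$data_type <- oc$data_type[match(key3(st), key3(oc))]
  st$position <- plot_positions(st)

  n_studies0 <- nrow(st)
  ph <- phantom_flags(st, options)
  removed_phantoms <- removal_keys(st[ph, , drop = FALSE])
  st1 <- st[!ph, , drop = FALSE]

  dup <- duplicate_flags(st1)
  removed_dups <- removal_keys(st1[dup, , drop = FALSE])
  st2 <- st1[!dup, , drop = FALSE]

  n_per_plot <- table(factor(key3(st2), levels = key3(oc)))
  plot_ok <- as.integer(n_per_plot) >= 2
  keep_keys <- key3(oc)[plot_ok]
  underfilled <- st2[!key3(st2) %in% keep_keys, , drop = FALSE]
  removed_underfilled <- removal_keys(underfilled)
  st3 <- st2[key3(st2) %in% keep_keys, , drop = FALSE]

  study_ledger <- flow_ledger(
    stages = c("phantom records", "within-plot duplicates",
               "in plots with <2 studies"),
    records_in = c(n_studies0, n_studies0 - sum(ph),
                   n_studies0 - sum(ph) - sum(dup)),
    excluded = c(sum(ph), sum(dup), nrow(underfilled)),
    reason = c("phantom zero-pattern record",
               "repeat occurrence of a study within one forest plot",
               "forest plot left with fewer than 2 distinct studies")
  )

  n_plots0 <- nrow(oc)
  meta_analysis_ledger <- flow_ledger(
    stages = "fewer than 2 distinct studies after cleaning",
    records_in = n_plots0,
    excluded = sum(!plot_ok),
    reason = "fewer than 2 distinct studies after cleaning"
  )

  oc2 <- oc[plot_ok, , drop = FALSE]
  cp <- db$comparisons
  cp2 <- cp[key2(cp) %in% key2(oc2), , drop = FALSE]
  rv <- db$reviews
  keep_reviews <- rv$review_id %in% oc2$review_id
  review_ledger <- flow_ledger(
    stages = "no eligible meta-analyses",
    records_in = nrow(rv),
    excluded = sum(!keep_reviews),
    reason = "no forest plot with at least 2 eligible studies"
  )
  rv2 <- rv[keep_reviews, , drop = FALSE]

  curated <- sr_database(
    rv2, cp2, oc2,
    st3[, c("review_id", "comparison_id", "outcome_id", "subgroup",
            "study_id", PAYLOAD_COLS)],
    issue_label = db$issue_label, validate = FALSE
  )

  structure(
    list(
      review_ledger = review_ledger,
      meta_analysis_ledger = meta_analysis_ledger,
      study_ledger = study_ledger,
      curated = curated,
      removed = list(
        phantoms = removed_phantoms,
        duplicates = removed_dups,
        underfilled = removed_underfilled
      )
    ),
    class = "curation_report"
  )
}

removal_keys <- function(rows) {
  out <- rows[, c("review_id", "comparison_id", "outcome_id", "subgroup",
                  "study_id", "position"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full curation pipeline
#'
#' [filter_reviews()] followed by [select_eligible_meta_analyses()], with
#' the review-level stages stitched into a single review ledger.
#'
#' @inheritParams select_eligible_meta_analyses
#' @return A `curation_report` (see [select_eligible_meta_analyses()]).
#' @export
curate <- function(db, options = curation_options()) {
  step1 <- filter_reviews(db)
  report <- select_eligible_meta_analyses(step1$db, options)
  report$review_ledger <- flow_ledger(
    stages = c(step1$ledger$stage, report$review_ledger$stage),
    records_in = c(step1$ledger$records_in, report$review_ledger$records_in),
    excluded = c(step1$ledger$excluded, report$review_ledger$excluded),
    reason = c(step1$ledger$reason, report$review_ledger$reason)
  )
  report
}

#' @export
print.curation_report <- function(x, ...) {
  cat("<curation_report>\n")
  cat(sprintf("  reviews:       %d in -> %d eligible\n",
              x$review_ledger$records_in[1], ledger_remaining(x$review_ledger)))
  cat(sprintf("  meta-analyses: %d in -> %d eligible\n",
              x$meta_analysis_ledger$records_in[1],
              ledger_remaining(x$meta_analysis_ledger)))
  cat(sprintf("  study rows:    %d in -> %d retained\n",
              x$study_ledger$records_in[1], ledger_remaining(x$study_ledger)))
  invisible(x)
}

#' Serialise a curation report
#'
#' Writes the three flow ledgers as one machine-readable CSV (columns
#' `ledger`, `stage`, `records_in`, `excluded`, `reason`) and, alongside
#' it, a human-readable flow summary text file.
#'
#' @param report a `curation_report`.
#' @param csv_path destination for the CSV ledger.
#' @param txt_path optional destination for the text summary.
#' @return `csv_path`, invisibly.
#' @export
write_curation_report <- function(report, csv_path, txt_path = NULL) {
  rows <- do.call(rbind, lapply(
    c("review_ledger", "meta_analysis_ledger", "study_ledger"),
    function(nm) {
      led <- as.data.frame(report[[nm]])
      if (!nrow(led)) return(NULL)
      cbind(ledger = sub("_ledger$", "", nm), led)
    }
  ))
  utils::write.csv(rows, csv_path, row.names = FALSE)
  if (!is.null(txt_path)) {
    lines <- c("Eligibility and exclusion flow", "")
    for (nm in c("review_ledger", "meta_analysis_ledger", "study_ledger")) {
      led <- report[[nm]]
      unit <- c(review_ledger = "reviews", meta_analysis_ledger = "meta-analyses",
                study_ledger = "study records")[[nm]]
      lines <- c(lines, sprintf("%s entering: %d", unit, led$records_in[1]))
      for (i in seq_len(nrow(led))) {
        lines <- c(lines, sprintf("  excluded at '%s': %d (%s)",
                                  led$stage[i], led$excluded[i], led$reason[i]))
      }
      lines <- c(lines, sprintf("%s remaining: %d", unit, ledger_remaining(led)), "")
    }
    writeLines(lines, txt_path)
  }
  invisible(csv_path)
}

#' Detect structural anomalies
#'
#' Flags, without modifying the data, entry mistakes of the kind that
#' occur when review data are typed into a hierarchical database:
#' sibling outcomes with identical names under one comparison (subgroups
#' listed as if they were separate outcomes), forest plots with missing
#' outcome names, and study rows whose payload pattern conflicts with the
#' plot's declared data type.
#'
#' @param db an [sr_database()].
#' @return A data frame with columns `type`, `path` and `message`; zero
#'   rows for a clean database.
#' @export
detect_structural_anomalies <- function(db) {
  stopifnot(is_sr_database(db))
  out <- list()
  oc <- db$outcomes
  if (nrow(oc)) {
    k <- paste(key2(oc), oc$name, sep = "\r")
    dup_names <- !is.na(oc$name) & (duplicated(k) | duplicated(k, fromLast = TRUE))
    for (i in which(dup_names)) {
      out[[length(out) + 1]] <- data.frame(
        type = "duplicate_outcome_name",
        path = key_path(oc[i, ]),
        message = sprintf(
          "outcome name '%s' appears more than once under comparison %s/%s (subgroups may be listed as separate outcomes)",
          oc$name[i], oc$review_id[i], oc$comparison_id[i]),
        stringsAsFactors = FALSE
      )
    }
    for (i in which(is.na(oc$name) | oc$name == "")) {
      out[[length(out) + 1]] <- data.frame(
        type = "missing_outcome_name",
        path = key_path(oc[i, ]),
        message = sprintf("forest plot %s has no outcome name", key_path(oc[i, ])),
        stringsAsFactors = FALSE
      )
    }
  }
  st <- db$studies
  if (nrow(st)) {
    dtype <- oc$data_type[match(key3(st), key3(oc))]
    mism <- payload_mismatch(st, dtype)
    for (i in which(mism)) {
      out[[length(out) + 1]] <- data.frame(
        type = "payload_type_conflict",
        path = key_path(st[i, ]),
        message = sprintf(
          "study '%s' in plot %s has payload fields inconsistent with declared data_type '%s'",
          st$study_id[i], key_path(st[i, ]), dtype[i]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(type = character(0), path = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
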