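# Interchange formats.
#
# JSON is the canonical, full-fidelity format: a nested hierarchy with a
# fixed key order and document record order, so save -> load -> save is
# byte-identical. The flat CSV carries one row per study entry with the
# ancestor attributes repeated; containers without any study row cannot be
# represented there and are dropped with a warning on save.

CSV_COLS <- c(
  "review_id", "review_title", "review_group", "status",
  "is_methodology_group", "specialty_label",
  "comparison_id", "comparison_name", "active_intervention_label",
  "comparator_label",
  "outcome_id", "outcome_name", "data_type", "totals_displayed",
  "outcome_category_label",
  "subgroup", "study_id", PAYLOAD_COLS
)

#' Read a systematic-review database from disk
#'
#' Reads either the canonical nested JSON hierarchy or the flat one-row-
#' per-study CSV, reconstructs the hierarchy and validates every
#' invariant. Malformed records raise an error naming the offending
#' record; invariant violations raise an error listing the path into the
#' hierarchy.
#'
#' @param path file to read.
#' @param format `"json"` or `"csv"`; the default guesses from the file
#'   extension.
#' @param strict if `TRUE`, structural anomalies detected by
#'   [detect_structural_anomalies()] are escalated to errors.
#' @return A validated [sr_database()].
#' @seealso [save_database()]
#' @export
load_database <- function(path, format = c("auto", "json", "csv"),
                          strict = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  db <- switch(format,
    json = load_database_json(path),
    csv  = load_database_csv(path)
  )
  validate_sr_database(db)
  if (strict) {
    anom <- detect_structural_anomalies(db)
    if (nrow(anom)) {
      stop("structural anomalies in ", path, ":\n  ",
           paste(utils::head(anom$message, 10), collapse = "\n  "),
           call. = FALSE)
    }
  }
  db
}

#' Write a systematic-review database to disk
#'
#' The JSON serialisation is canonical: fixed key order, record order as
#' in the database, two-space indentation, `null` for absent optional
#' fields (a generic or O-E payload with no recorded `total_n` is written
#' with an explicit `null`). Loading and re-saving a canonical file
#' reproduces it byte for byte.
#'
#' @param db a valid [sr_database()].
#' @param path destination file.
#' @param format `"json"` or `"csv"`; the default guesses from the
#'   extension.
#' @return `path`, invisibly.
#' @export
save_database <- function(db, path, format = c("auto", "json", "csv")) {
  stopifnot(is_sr_database(db))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  switch(format,
    json = save_database_json(db, path),
    csv  = save_database_csv(db, path)
  )
  invisible(path)
}

## ---- JSON ------------------------------------------------------------

jnull <- function(x) if (length(x) != 1 || is.na(x)) NULL else unname(x)

save_database_json <- function(db, path) {
  rv <- db$reviews; cp <- db$comparisons; oc <- db$outcomes; st <- db$studies
  reviews <- lapply(seq_len(nrow(rv)), function(i) {
    r <- rv[i, ]
    cps <- cp[cp$review_id == r$review_id, , drop = FALSE]
    comparisons <- lapply(seq_len(nrow(cps)), function(j) {
      cc <- cps[j, ]
      ocs <- oc[oc$review_id == cc$review_id &
                oc$comparison_id == cc$comparison_id, , drop = FALSE]
      outcomes <- lapply(seq_len(nrow(ocs)), function(k) {
        oo <- ocs[k, ]
        ss <- st[key3(st) == key3(oo), , drop = FALSE]
        sgs <- unique(ss$subgroup)
        subgroups <- lapply(sgs, function(sg) {
          rows <- ss[ss$subgroup == sg, , drop = FALSE]
          list(
            name = sg,
            studies = lapply(seq_len(nrow(rows)), function(m)
              serialize_study(rows[m, ], oo$data_type))
          )
        })
        out <- list(
          outcome_id = oo$outcome_id,
          name = jnull(oo$name),
          data_type = oo$data_type,
          totals_displayed = oo$totals_displayed,
          outcome_category_label = jnull(oo$outcome_category_label),
          subgroups = subgroups
        )
        out["name"] <- list(out$name)  # keep explicit null
        out["outcome_category_label"] <- list(out$outcome_category_label)
        out
      })
      out <- list(
        comparison_id = cc$comparison_id,
        name = jnull(cc$name),
        active_intervention_label = jnull(cc$active_intervention_label),
        comparator_label = jnull(cc$comparator_label),
        outcomes = outcomes
      )
      for (f in c("name", "active_intervention_label", "comparator_label"))
        out[f] <- list(out[[f]])
      out
    })
    out <- list(
      review_id = r$review_id,
      title = jnull(r$title),
      review_group = jnull(r$review_group),
      status = r$status,
      is_methodology_group = r$is_methodology_group,
      specialty_label = jnull(r$specialty_label),
      comparisons = comparisons
    )
    for (f in c("title", "review_group", "specialty_label"))
      out[f] <- list(out[[f]])
    out
  })
  doc <- list(issue_label = db$issue_label, reviews = reviews)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                           na = "null", digits = NA, pretty = 2,
                           always_decimal = FALSE)
  writeLines(json, path, useBytes = TRUE)
}

serialize_study <- function(row, data_type) {
  fields <- c(REQUIRED_PAYLOAD[[data_type]], OPTIONAL_PAYLOAD[[data_type]])
  out <- list(study_id = row$study_id)
  for (f in fields) out[f] <- list(jnull(row[[f]]))
  out
}

load_database_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.list(doc) || is.null(doc$reviews))
    stop("malformed database file ", path, ": missing 'reviews'", call. = FALSE)

  rv <- list(); cp <- list(); oc <- list(); st <- list()
  sc <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  sn <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  sl <- function(x) if (is.null(x)) NA else as.logical(x)

  for (r in doc$reviews) {
    if (is.null(r$review_id))
      stop("malformed record: review without review_id", call. = FALSE)
    rid <- sc(r$review_id)
    rv[[length(rv) + 1]] <- data.frame(
      review_id = rid, title = sc(r$title), review_group = sc(r$review_group),
      status = sc(r$status), is_methodology_group = sl(r$is_methodology_group),
      specialty_label = sc(r$specialty_label), stringsAsFactors = FALSE
    )
    for (cc in r$comparisons) {
      if (is.null(cc$comparison_id))
        stop("malformed record: comparison without comparison_id under review ",
             rid, call. = FALSE)
      cid <- sc(cc$comparison_id)
      cp[[length(cp) + 1]] <- data.frame(
        review_id = rid, comparison_id = cid, name = sc(cc$name),
        active_intervention_label = sc(cc$active_intervention_label),
        comparator_label = sc(cc$comparator_label), stringsAsFactors = FALSE
      )
      for (oo in cc$outcomes) {
        if (is.null(oo$outcome_id) || is.null(oo$data_type))
          stop("malformed record: outcome without outcome_id/data_type under ",
               rid, "/", cid, call. = FALSE)
        oid <- sc(oo$outcome_id)
        dt <- sc(oo$data_type)
        oc[[length(oc) + 1]] <- data.frame(
          review_id = rid, comparison_id = cid, outcome_id = oid,
          name = sc(oo$name), data_type = dt,
          totals_displayed = sl(oo$totals_displayed),
          outcome_category_label = sc(oo$outcome_category_label),
          stringsAsFactors = FALSE
        )
        for (sg in oo$subgroups) {
          sgname <- sc(sg$name)
          for (ss in sg$studies) {
            if (is.null(ss$study_id))
              stop("malformed record: study without study_id in plot ",
                   rid, "/", cid, "/", oid, call. = FALSE)
            row <- data.frame(
              review_id = rid, comparison_id = cid, outcome_id = oid,
              subgroup = sgname, study_id = sc(ss$study_id),
              stringsAsFactors = FALSE
            )
            for (col in PAYLOAD_COLS) row[[col]] <- sn(ss[[col]])
            st[[length(st) + 1]] <- row
          }
        }
      }
    }
  }
  sr_database(
    reviews = bind_rows_list(rv, empty_reviews()),
    comparisons = bind_rows_list(cp, empty_comparisons()),
    outcomes = bind_rows_list(oc, empty_outcomes()),
    studies = bind_rows_list(st, empty_studies()),
    issue_label = if (is.null(doc$issue_label)) "unlabelled" else doc$issue_label,
    validate = FALSE
  )
}

bind_rows_list <- function(lst, template) {
  if (!length(lst)) return(template)
  as.data.frame(data.table::rbindlist(lst, use.names = TRUE, fill = TRUE))
}

## ---- CSV -------------------------------------------------------------

save_database_csv <- function(db, path) {
  st <- study_table(db)
  n_total <- nrow(db$reviews) + nrow(db$comparisons) + nrow(db$outcomes)
  n_repr <- length(unique(st$review_id)) +
    length(unique(key2(st))) + length(unique(key3(st)))
  if (n_repr < n_total) {
    warning("CSV export drops containers without study rows; ",
            "use JSON for full fidelity", call. = FALSE)
  }
  rv <- db$reviews; cp <- db$comparisons; oc <- db$outcomes
  m <- match(st$review_id, rv$review_id)
  out <- data.frame(
    review_id = st$review_id,
    review_title = rv$title[m],
    review_group = rv$review_group[m],
    status = rv$status[m],
    is_methodology_group = rv$is_methodology_group[m],
    specialty_label = rv$specialty_label[m],
    comparison_id = st$comparison_id,
    comparison_name = cp$name[match(key2(st), key2(cp))],
    active_intervention_label = st$active_intervention_label,
    comparator_label = st$comparator_label,
    outcome_id = st$outcome_id,
    outcome_name = oc$name[match(key3(st), key3(oc))],
    data_type = st$data_type,
    totals_displayed = oc$totals_displayed[match(key3(st), key3(oc))],
    outcome_category_label = st$outcome_category_label,
    subgroup = st$subgroup,
    study_id = st$study_id,
    stringsAsFactors = FALSE
  )
  for (col in PAYLOAD_COLS) out[[col]] <- st[[col]]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

load_database_csv <- function(path) {
  chr_cols <- c("review_id", "review_title", "review_group", "status",
                "specialty_label", "comparison_id", "comparison_name",
                "active_intervention_label", "comparator_label",
                "outcome_id", "outcome_name", "data_type",
                "outcome_category_label", "subgroup", "study_id")
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = stats::setNames(rep("character", length(chr_cols)),
                                                 chr_cols)),
    error = function(e) stop("malformed CSV in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  missing <- setdiff(CSV_COLS, names(raw))
  if (length(missing))
    stop("malformed CSV in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  raw[raw == ""] <- NA
  for (col in PAYLOAD_COLS) raw[[col]] <- as.numeric(raw[[col]])
  raw$is_methodology_group <- as.logical(raw$is_methodology_group)
  raw$totals_displayed <- as.logical(raw$totals_displayed)
  raw$subgroup[is.na(raw$subgroup)] <- "All studies"

  rv <- raw[!duplicated(raw$review_id),
            c("review_id", "review_title", "review_group", "status",
              "is_methodology_group", "specialty_label")]
  names(rv)[2] <- "title"
  cp <- raw[!duplicated(key2(raw)),
            c("review_id", "comparison_id", "comparison_name",
              "active_intervention_label", "comparator_label")]
  names(cp)[3] <- "name"
  oc <- raw[!duplicated(key3(raw)),
            c("review_id", "comparison_id", "outcome_id", "outcome_name",
              "data_type", "totals_displayed", "outcome_category_label")]
  names(oc)[4] <- "name"
  st <- raw[, c("review_id", "comparison_id", "outcome_id", "subgroup",
                "study_id", PAYLOAD_COLS)]
  sr_database(rv, cp, oc, st, issue_label = basename(path), validate = FALSE)
}
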