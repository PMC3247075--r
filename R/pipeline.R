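# End-to-end pipeline: load (or simulate) -> validate labels -> curate ->
# summarise, writing the curated database, the flow ledgers and the six
# standard summary tables to an output directory. All outputs are plain
# text and deterministic given identical inputs, so repeated runs are
# byte-identical.

#' Run configuration
#'
#' @param input path to a database file (JSON or CSV).
#' @param out_dir output directory (created if needed).
#' @param vocab_path optional vocabulary configuration file; the shipped
#'   default is used when `NULL`.
#' @param percent_style percentage dialect for the one-way tables, see
#'   [render_percent()].
#' @param ma_probs quantile probabilities for meta-analysis size tables.
#' @param size_probs quantile probabilities for sample-size tables.
#' @param strict if `TRUE` (default), label violations abort the run;
#'   otherwise they are reported and the offending dimension's tables
#'   are still attempted.
#' @param options a [curation_options()] object.
#' @param verbose print stage-by-stage progress.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input, out_dir, vocab_path = NULL,
                       percent_style = "integer_floor_label",
                       ma_probs = c(0.5, 0.75, 0.9, 0.99),
                       size_probs = c(0.25, 0.5, 0.75),
                       strict = TRUE, options = curation_options(),
                       verbose = TRUE) {
  structure(
    list(input = input, out_dir = out_dir, vocab_path = vocab_path,
         percent_style = percent_style, ma_probs = ma_probs,
         size_probs = size_probs, strict = isTRUE(strict),
         options = options, verbose = isTRUE(verbose)),
    class = "run_config"
  )
}

#' Run the census pipeline
#'
#' Loads a database, checks every classification label against the
#' vocabularies (aborting in strict mode on any violation), runs the
#' curation pipeline, and writes to the output directory: the curated
#' database (`curated.json`), the machine-readable flow ledger
#' (`flow_ledger.csv`) with a human-readable mirror (`flow_summary.txt`),
#' label violations if any (`label_violations.csv`), and the six summary
#' tables `table1.csv` (specialty), `table2.csv` (intervention
#' cross-tab), `table3.csv` (outcome categories), `table4.csv`
#' (review composition), `table5.csv` (studies per meta-analysis, overall
#' and by data type, specialty, comparison group and outcome group) and
#' `table6.csv` (study sample size, same strata), plus a machine-readable
#' `summary.json` with the headline counts.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the `curation_report`, the paths of
#'   all written artifacts, and the label `violations` data frame.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))
  if (!file.exists(config$input))
    stop("input not found: ", config$input, call. = FALSE)
  vocabs <- default_vocabularies(config$vocab_path)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  db <- load_database(config$input)
  say("loaded %s: %d reviews, %d plots, %d study rows",
      config$input, n_reviews(db), n_meta_analyses(db), n_study_rows(db))

  report <- curate(db, config$options)
  cur <- report$curated
  say("curated: %d reviews, %d meta-analyses, %d study rows",
      n_reviews(cur), n_meta_analyses(cur), n_study_rows(cur))

  violations <- validate_labels(cur, vocabs)
  if (nrow(violations)) {
    paths$label_violations <- file.path(config$out_dir, "label_violations.csv")
    utils::write.csv(violations, paths$label_violations, row.names = FALSE)
    if (config$strict) {
      stop("label validation failed: ", nrow(violations),
           " violation(s); see ", paths$label_violations, call. = FALSE)
    }
    say("label validation: %d violation(s) (lenient mode)", nrow(violations))
  }

  paths$curated <- file.path(config$out_dir, "curated.json")
  save_database(cur, paths$curated)
  paths$flow_ledger <- file.path(config$out_dir, "flow_ledger.csv")
  paths$flow_summary <- file.path(config$out_dir, "flow_summary.txt")
  write_curation_report(report, paths$flow_ledger, paths$flow_summary)

  # in lenient mode a table whose labels cannot be classified is skipped
  # (with a message) instead of aborting the run
  wt <- function(name, expr) {
    df <- if (config$strict) expr else
      tryCatch(expr, error = function(e) {
        say("skipping %s: %s", name, conditionMessage(e))
        NULL
      })
    if (is.null(df)) return(NULL)
    p <- file.path(config$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  paths$table1 <- wt("table1.csv",
                     count_by(cur, "specialty", vocabs, config$percent_style))
  paths$table2 <- wt("table2.csv", {
    ct <- crosstab_interventions(cur, vocabs)
    t2 <- as.data.frame(ct$counts)
    t2 <- cbind(active = rownames(ct$counts), t2, total = ct$row_totals)
    rbind(t2, c(active = "Total", as.list(ct$col_totals),
                total = ct$grand_total))
  })
  paths$table3 <- wt("table3.csv",
                     count_by(cur, "outcome_category", vocabs,
                              "one_decimal_small"))
  paths$table4 <- wt("table4.csv", per_review_summary(cur))
  stack_groupings <- function(unit, probs) {
    blocks <- lapply(c("none", "data_type_group", "specialty", "collapsed5",
                       "outcome_group11"), function(g) {
      qs <- grouped_quantiles(cur, unit, g, probs, vocabs)
      cbind(stratum = g, as.data.frame(qs))
    })
    do.call(rbind, blocks)
  }
  paths$table5 <- wt("table5.csv",
                     stack_groupings("studies_per_meta_analysis",
                                     config$ma_probs))
  paths$table6 <- wt("table6.csv",
                     stack_groupings("study_sample_size", config$size_probs))
  paths <- Filter(Negate(is.null), paths)

  summary_doc <- list(
    input = basename(config$input),
    reviews_in = n_reviews(db),
    reviews_eligible = n_reviews(cur),
    meta_analyses_eligible = n_meta_analyses(cur),
    study_rows_retained = n_study_rows(cur),
    label_violations = nrow(violations)
  )
  paths$summary <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary_doc, paths$summary, auto_unbox = TRUE,
                       pretty = TRUE)
  say("wrote %d artifacts to %s", length(paths), config$out_dir)
  invisible(list(report = report, paths = paths, violations = violations))
}

#' Simulate a database to disk
#'
#' Convenience wrapper: [generate_database()] with a [default_config()]
#' and canonical JSON output, for feeding [run_pipeline()].
#'
#' @param path destination JSON file.
#' @param n_reviews,seed passed to [default_config()].
#' @param ... further [generator_config()] overrides.
#' @return Invisibly, the ground truth of the generated database.
#' @export
simulate_database <- function(path, n_reviews = 500, seed = 1L, ...) {
  gen <- generate_database(default_config(n_reviews = n_reviews,
                                          seed = seed, ...))
  save_database(gen$db, path)
  invisible(gen$ground_truth)
}
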