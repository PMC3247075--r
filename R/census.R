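# Descriptive census engine: one-way category tables, the 15x5
# intervention cross-tabulation and its five-way collapse, per-review
# composition summaries, grouped quantile tables for meta-analysis size
# and study sample size, percentage rendering in the two table dialects,
# and a tie-aware Wilcoxon rank-sum comparison.

#' Census quantiles
#'
#' Quantiles by linear interpolation between order statistics at
#' position `(n-1)p + 1` (`stats::quantile` type 7), the convention used
#' throughout the package; it returns integer medians and quartiles on
#' integer count data whenever the interpolation lands on an order
#' statistic.
#'
#' @param x numeric vector (missing values removed).
#' @param probs probabilities.
#' @return Numeric vector of quantiles.
#' @export
#' @examples
#' census_quantile(c(1, 2, 3, 4), 0.25)  # 1.75
census_quantile <- function(x, probs) {
  x <- x[!is.na(x)]
  unname(stats::quantile(x, probs = probs, type = 7, names = FALSE))
}

#' Render a percentage in table style
#'
#' Two dialects are supported. `"integer_floor_label"`: a count of zero
#' renders `"0%"`; a nonzero share strictly below 1% renders `"<1%"`;
#' anything else renders as the nearest integer percent (half away from
#' zero). `"one_decimal_small"`: shares below 1% are shown with one
#' decimal place (e.g. `"0.4%"`), larger shares as nearest-integer
#' percents.
#'
#' @param count numerator count (vectorised).
#' @param total positive denominator.
#' @param style `"integer_floor_label"` or `"one_decimal_small"`.
#' @return Character vector of rendered percentages.
#' @export
#' @examples
#' render_percent(186, 22453)   # "<1%"
#' render_percent(4027, 22453)  # "18%"
#' render_percent(94, 22453, "one_decimal_small")  # "0.4%"
render_percent <- function(count, total,
                           style = c("integer_floor_label", "one_decimal_small")) {
  style <- match.arg(style)
  if (length(total) != 1 || is.na(total) || total <= 0)
    stop("total must be a single positive count", call. = FALSE)
  if (any(count > total)) stop("count exceeds total", call. = FALSE)
  pct <- 100 * count / total
  round_half_up <- function(x) floor(x + 0.5)
  out <- paste0(round_half_up(pct), "%")
  if (style == "integer_floor_label") {
    out[count > 0 & pct < 1] <- "<1%"
    out[count == 0] <- "0%"
  } else {
    small <- pct < 1
    out[small] <- paste0(formatC(pct[small], format = "f", digits = 1), "%")
  }
  out
}

#' One-way census table
#'
#' Counts eligible meta-analyses (forest plots) along one classification
#' dimension, including zero-count categories, with rendered
#' percentages. Every plot must carry the label the dimension needs; a
#' missing label raises an error naming the plot.
#'
#' @param db a curated [sr_database()].
#' @param dimension `"specialty"`, `"outcome_category"` or
#'   `"data_type_group"`.
#' @param vocabs a [vocabularies()] bundle.
#' @param style percentage style, see [render_percent()].
#' @return A data frame of class `one_way_table` with columns `category`,
#'   `count`, `percent`, and attributes `total` and `dimension`. An empty
#'   database yields all-zero counts with percentages rendered as an
#'   em-dash.
#' @export
count_by <- function(db, dimension = c("specialty", "outcome_category",
                                       "data_type_group"),
                     vocabs = default_vocabularies(),
                     style = "integer_floor_label") {
  dimension <- match.arg(dimension)
  pt <- plot_table(db)
  spec <- switch(dimension,
    specialty = list(label = pt$specialty_label,
                     levels = as.character(vocabs$specialty),
                     field = "specialty_label"),
    outcome_category = list(label = pt$outcome_category_label,
                            levels = vocabs$outcome$categories,
                            field = "outcome_category_label"),
    data_type_group = list(label = unname(vocabs$data_type_group[pt$data_type]),
                           levels = unique(unname(vocabs$data_type_group)),
                           field = "data_type")
  )
  if (anyNA(spec$label) && nrow(pt)) {
    bad <- pt[is.na(spec$label), , drop = FALSE][1, ]
    stop("missing ", spec$field, " on forest plot ", key_path(bad),
         call. = FALSE)
  }
  unknown <- setdiff(unique(spec$label), spec$levels)
  if (length(unknown))
    stop("label(s) outside vocabulary for ", dimension, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  counts <- table(factor(spec$label, levels = spec$levels))
  total <- sum(counts)
  out <- data.frame(category = spec$levels, count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$percent <- if (total > 0) render_percent(out$count, total, style)
                 else rep("—", nrow(out))
  attr(out, "total") <- total
  attr(out, "dimension") <- dimension
  class(out) <- c("one_way_table", "data.frame")
  out
}

#' Cross-tabulation with conserved margins
#'
#' Wraps a counts matrix with its row totals, column totals and grand
#' total. Structurally impossible cells are carried as `NA` and treated
#' as zero in every margin.
#'
#' @param counts numeric matrix with row and column names.
#' @return A list of class `cross_tab` with elements `counts`,
#'   `row_totals`, `col_totals` and `grand_total`.
#' @export
cross_tab <- function(counts) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0, na.rm = TRUE)) stop("negative cell count", call. = FALSE)
  structure(
    list(
      counts = counts,
      row_totals = rowSums(counts, na.rm = TRUE),
      col_totals = colSums(counts, na.rm = TRUE),
      grand_total = sum(counts, na.rm = TRUE)
    ),
    class = "cross_tab"
  )
}

#' @export
print.cross_tab <- function(x, ...) {
  cat("<cross_tab> grand total:", x$grand_total, "\n")
  disp <- x$counts
  shown <- matrix(
    ifelse(is.na(disp), "n/a",
           paste0(disp, " (", render_percent(ifelse(is.na(disp), 0, disp),
                                             max(x$grand_total, 1)), ")")),
    nrow = nrow(disp), dimnames = dimnames(disp)
  )
  shown <- cbind(shown, Total = as.character(x$row_totals))
  print(shown, quote = FALSE)
  cat("Column totals:", paste(x$col_totals, collapse = " "), "\n")
  invisible(x)
}

#' Intervention cross-tabulation of a curated database
#'
#' Counts eligible meta-analyses in each (active intervention,
#' comparator kind) cell of the 15-by-5 table. The cell pairing the
#' pharmacological active category with a same-category
#' non-pharmacological comparator is structurally excluded (`NA`).
#' Every plot's comparison must carry classifiable intervention labels.
#'
#' @param db a curated [sr_database()].
#' @param vocabs a [vocabularies()] bundle.
#' @return A [cross_tab()].
#' @export
crosstab_interventions <- function(db, vocabs = default_vocabularies()) {
  iv <- vocabs$intervention
  pt <- plot_table(db)
  if (nrow(pt) &&
      (anyNA(pt$active_intervention_label) || anyNA(pt$comparator_label))) {
    bad <- pt[is.na(pt$active_intervention_label) |
              is.na(pt$comparator_label), , drop = FALSE][1, ]
    stop("unclassified comparison for forest plot ", key_path(bad),
         call. = FALSE)
  }
  counts <- matrix(0L, nrow = length(iv$active), ncol = length(COMPARATOR_KINDS),
                   dimnames = list(iv$active, COMPARATOR_KINDS))
  if (nrow(pt)) {
    pairs <- unique(pt[, c("active_intervention_label", "comparator_label")])
    for (i in seq_len(nrow(pairs))) {
      cls <- classify_comparison(pairs$active_intervention_label[i],
                                 pairs$comparator_label[i], iv)
      n <- sum(pt$active_intervention_label == pairs[i, 1] &
               pt$comparator_label == pairs[i, 2])
      counts[cls$active_category, cls$comparator_kind] <-
        counts[cls$active_category, cls$comparator_kind] + n
    }
  }
  counts[iv$pharmacological, "same-category non-pharm"] <- NA
  cross_tab(counts)
}

#' Collapse an intervention cross-tab onto the five comparison groups
#'
#' Maps each cell of the 15-by-5 table onto the five-way grouping used
#' for stratified summaries (pharmacological or not, against
#' control/placebo, another drug, or another non-drug intervention) and
#' sums. The five group counts always re-sum to the cross-tab's grand
#' total.
#'
#' @param ct a [cross_tab()] as from [crosstab_interventions()].
#' @param vocab an [intervention_vocab()].
#' @return Named integer vector over the five groups.
#' @export
collapse_crosstab <- function(ct, vocab = default_vocabularies()$intervention) {
  stopifnot(inherits(ct, "cross_tab"))
  counts <- ct$counts
  out <- stats::setNames(numeric(length(COLLAPSED5)), COLLAPSED5)
  pharm <- vocab$pharmacological
  for (active in rownames(counts)) {
    for (kind in colnames(counts)) {
      n <- counts[active, kind]
      if (is.na(n) || n == 0) next
      comparator <- switch(kind,
        "Control" = "Control", "Placebo" = "Placebo",
        "Pharmacological" = pharm,
        "same-category non-pharm" = active,
        "different-category non-pharm" =
          setdiff(vocab$active, c(active, pharm))[1]
      )
      grp <- classify_comparison(active, comparator, vocab)$collapsed5
      out[grp] <- out[grp] + n
    }
  }
  out
}

#' Review-composition summaries
#'
#' Five-number summaries (min, lower quartile, median, upper quartile,
#' max) of the number of comparisons per review, the number of outcomes
#' (forest plots) per comparison, and the number of meta-analyses per
#' review, over a curated database.
#'
#' @param db a curated [sr_database()].
#' @return A data frame of class `quantile_summary` with one row per
#'   measure and columns `measure`, `n`, `min`, `p25`, `p50`, `p75`,
#'   `max`; zero rows for an empty database.
#' @export
per_review_summary <- function(db) {
  if (!n_reviews(db)) {
    out <- data.frame(measure = character(0), n = integer(0), min = numeric(0),
                      p25 = numeric(0), p50 = numeric(0), p75 = numeric(0),
                      max = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("quantile_summary", "data.frame")
    return(out)
  }
  comp_per_review <- as.integer(table(
    factor(db$comparisons$review_id, levels = db$reviews$review_id)))
  out_per_comp <- as.integer(table(
    factor(key2(db$outcomes), levels = key2(db$comparisons))))
  ma_per_review <- as.integer(table(
    factor(db$outcomes$review_id, levels = db$reviews$review_id)))
  five <- function(x) c(min(x), census_quantile(x, c(0.25, 0.5, 0.75)), max(x))
  rows <- rbind(five(comp_per_review), five(out_per_comp), five(ma_per_review))
  out <- data.frame(
    measure = c("comparisons per review", "outcomes per comparison",
                "meta-analyses per review"),
    n = c(length(comp_per_review), length(out_per_comp),
          length(ma_per_review)),
    min = rows[, 1], p25 = rows[, 2], p50 = rows[, 3], p75 = rows[, 4],
    max = rows[, 5], stringsAsFactors = FALSE
  )
  class(out) <- c("quantile_summary", "data.frame")
  out
}

#' Grouped quantile summaries
#'
#' Quantile tables for either the number of studies per meta-analysis
#' (one value per eligible forest plot) or the participant sample size
#' of individual study entries (one value per study row; rows whose
#' sample size is not recorded are excluded and counted in the
#' `n_missing` attribute). Units can be summarised overall
#' (`grouping = "none"`) or partitioned by data-type group, medical
#' specialty, five-way intervention comparison group, or the 11-group
#' outcome collapse; every unit falls in exactly one group, so group
#' sizes always sum to the overall count.
#'
#' @param db a curated [sr_database()].
#' @param unit `"studies_per_meta_analysis"` or `"study_sample_size"`.
#' @param grouping `"none"`, `"data_type_group"`, `"specialty"`,
#'   `"collapsed5"` or `"outcome_group11"`.
#' @param probs quantile probabilities (defaults: 50/75/90/99% for
#'   meta-analysis size, 25/50/75% for sample size).
#' @param vocabs a [vocabularies()] bundle.
#' @return A data frame of class `quantile_summary`: one row per group
#'   with columns `group`, `n`, one `pXX` column per probability, and
#'   `max`.
#' @export
grouped_quantiles <- function(db,
                              unit = c("studies_per_meta_analysis",
                                       "study_sample_size"),
                              grouping = c("none", "data_type_group",
                                           "specialty", "collapsed5",
                                           "outcome_group11"),
                              probs = NULL,
                              vocabs = default_vocabularies()) {
  unit <- match.arg(unit)
  grouping <- match.arg(grouping)
  if (is.null(probs)) {
    probs <- if (unit == "studies_per_meta_analysis") c(0.5, 0.75, 0.9, 0.99)
             else c(0.25, 0.5, 0.75)
  }
  tab <- if (unit == "studies_per_meta_analysis") plot_table(db) else study_table(db)
  values <- if (unit == "studies_per_meta_analysis") tab$n_studies else tab$sample_size

  group <- switch(grouping,
    none = rep("Total", nrow(tab)),
    data_type_group = unname(vocabs$data_type_group[tab$data_type]),
    specialty = tab$specialty_label,
    collapsed5 = collapsed5_of(tab, vocabs$intervention),
    outcome_group11 = collapse_outcome_group(tab$outcome_category_label,
                                             vocabs$outcome_group11)
  )
  if (anyNA(group) && nrow(tab))
    stop("missing label for grouping '", grouping, "' on unit ",
         key_path(tab[which(is.na(group))[1], ]), call. = FALSE)

  n_missing <- sum(is.na(values))
  keep <- !is.na(values)
  values <- values[keep]; group <- group[keep]

  levels <- switch(grouping,
    none = "Total",
    data_type_group = unique(unname(vocabs$data_type_group)),
    specialty = as.character(vocabs$specialty),
    collapsed5 = COLLAPSED5,
    outcome_group11 = unique(unname(vocabs$outcome_group11))
  )
  group <- factor(group, levels = levels)
  qcols <- paste0("p", sub("\\.0+$", "", as.character(round(100 * probs, 2))))
  rows <- lapply(levels, function(g) {
    v <- values[group == g]
    if (!length(v)) {
      row <- data.frame(group = g, n = 0L, stringsAsFactors = FALSE)
      for (qc in qcols) row[[qc]] <- NA_real_
      row$max <- NA_real_
      return(row)
    }
    row <- data.frame(group = g, n = length(v), stringsAsFactors = FALSE)
    q <- census_quantile(v, probs)
    for (i in seq_along(qcols)) row[[qcols[i]]] <- q[i]
    row$max <- max(v)
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "unit") <- unit
  attr(out, "grouping") <- grouping
  attr(out, "n_missing") <- n_missing
  class(out) <- c("quantile_summary", "data.frame")
  out
}

# five-way comparison group of each row of a plot/study table
collapsed5_of <- function(tab, vocab) {
  if (!nrow(tab)) return(character(0))
  pairs <- unique(tab[, c("active_intervention_label", "comparator_label")])
  pairs$grp <- vapply(seq_len(nrow(pairs)), function(i) {
    if (is.na(pairs$active_intervention_label[i]) ||
        is.na(pairs$comparator_label[i])) return(NA_character_)
    classify_comparison(pairs$active_intervention_label[i],
                        pairs$comparator_label[i], vocab)$collapsed5
  }, character(1))
  k <- paste(tab$active_intervention_label, tab$comparator_label, sep = "\r")
  pk <- paste(pairs$active_intervention_label, pairs$comparator_label, sep = "\r")
  pairs$grp[match(k, pk)]
}

#' Tie-aware Wilcoxon rank-sum test
#'
#' Two-sided test of stochastic equality between two samples, using
#' mid-ranks for ties. For combined sample sizes of 20 or fewer the
#' p-value is computed by exact enumeration of all group assignments of
#' the pooled values (valid under ties); otherwise a normal
#' approximation with tie-corrected variance and a 0.5 continuity
#' correction is used.
#'
#' @param x,y non-empty numeric vectors.
#' @param method `"auto"` (enumeration when `length(x) + length(y) <=
#'   20`), `"exact"` or `"normal"`.
#' @return A list of class `rank_sum_result` with elements `U` (the
#'   Mann-Whitney statistic for `x`), `method`, `z` (normal
#'   approximation only) and `p_two_sided`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_two_sided  # 0.1
wilcoxon_rank_sum <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in samples", call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)  # mid-ranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (method == "auto") method <- if (N <= 20) "exact" else "normal"

  if (method == "exact") {
    combs <- utils::combn(N, n1)
    rank_sums <- colSums(matrix(r[combs], nrow = n1))
    Us <- rank_sums - n1 * (n1 + 1) / 2
    centre <- n1 * n2 / 2
    dev <- abs(U - centre)
    p <- mean(abs(Us - centre) >= dev - 1e-9)
    return(structure(list(U = U, method = "exact", z = NULL,
                          p_two_sided = p), class = "rank_sum_result"))
  }

  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  var_U <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  centre <- n1 * n2 / 2
  if (var_U <= 0) {  # all values identical
    return(structure(list(U = U, method = "normal-approximation", z = 0,
                          p_two_sided = 1), class = "rank_sum_result"))
  }
  cc <- min(0.5, abs(U - centre))  # continuity correction toward the centre
  z <- (abs(U - centre) - cc) / sqrt(var_U)
  p <- min(1, 2 * stats::pnorm(-z))
  structure(list(U = U, method = "normal-approximation", z = z,
                 p_two_sided = p), class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: U = %g (%s), two-sided p = %.4g\n",
              x$U, x$method, x$p_two_sided))
  invisible(x)
}

#' Compare meta-analysis sizes for one outcome group against the rest
#'
#' Convenience wrapper over [wilcoxon_rank_sum()]: numbers of studies
#' per meta-analysis in forest plots whose collapsed outcome group
#' matches `group` versus all other eligible plots.
#'
#' @param db a curated [sr_database()].
#' @param group one of the 11 collapsed outcome group names (e.g.
#'   `"All-cause mortality"`).
#' @param vocabs a [vocabularies()] bundle.
#' @inheritParams wilcoxon_rank_sum
#' @return A `rank_sum_result`.
#' @export
compare_study_counts <- function(db, group, vocabs = default_vocabularies(),
                                 method = "auto") {
  pt <- plot_table(db)
  g11 <- collapse_outcome_group(pt$outcome_category_label,
                                vocabs$outcome_group11)
  if (!group %in% unname(vocabs$outcome_group11))
    stop("unknown outcome group: ", group, call. = FALSE)
  x <- pt$n_studies[g11 == group]
  y <- pt$n_studies[g11 != group]
  wilcoxon_rank_sum(x, y, method = method)
}
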