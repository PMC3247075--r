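# Calibrated synthetic review databases.
#
# The generator emulates the statistical structure the census assumes:
# a review hierarchy whose branching factors, study counts, sample sizes
# and category labels follow the marginal distributions published for a
# complete issue of the Cochrane Database of Systematic Reviews (Issue 1,
# 2008), plus controlled contamination (phantom zero-pattern records,
# within-plot duplicates, protocol/withdrawn reviews) with full ground
# truth, so the cleaning rules can be checked for exact recovery.

#' Published reference marginals
#'
#' The category marginals and cross-tabulation published for the
#' January 2008 issue of the Cochrane Database of Systematic Reviews
#' (22,453 eligible meta-analyses), shipped as plain CSV under
#' `inst/extdata`: the 11-specialty one-way table, the 15-by-5
#' intervention cross-tabulation (with the structurally empty
#' pharmacological/same-category cell as `NA`) and the 23-category
#' outcome one-way table. These calibrate the generator's label
#' distributions and drive the worked-example algebra.
#'
#' @return A list with elements `specialty` (data frame `category`,
#'   `count`), `intervention` (matrix, active categories by comparator
#'   kinds) and `outcome` (data frame `category`, `count`).
#' @export
reference_marginals <- function() {
  dir <- system.file("extdata", package = "srcensus")
  spec <- utils::read.csv(file.path(dir, "specialty_marginals.csv"),
                          stringsAsFactors = FALSE)
  outc <- utils::read.csv(file.path(dir, "outcome_marginals.csv"),
                          stringsAsFactors = FALSE)
  raw <- utils::read.csv(file.path(dir, "intervention_crosstab.csv"),
                         stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(raw[, -1])
  rownames(m) <- raw$active
  list(specialty = spec, intervention = m, outcome = outc)
}

#' Distribution specifications
#'
#' Small declarative specs for the generator's branching and size
#' distributions, so each family can be swapped without code changes:
#' \describe{
#'   \item{`dist_shifted_nbinom(shift, size, mu, cap)`}{`shift` plus a
#'     negative binomial, right-capped at `cap`.}
#'   \item{`dist_shifted_geometric(p, cap)`}{1 plus a geometric
#'     (support 1, 2, ...), right-capped.}
#'   \item{`dist_lognormal_int(meanlog, sdlog, min)`}{log-normal rounded
#'     to integers with a lower floor.}
#' }
#' `draw_dist(spec, n)` draws `n` values from any of them.
#'
#' @param shift,size,mu,cap,p,meanlog,sdlog,min family parameters.
#' @return A list of class `dist_spec`.
#' @export
dist_shifted_nbinom <- function(shift, size, mu, cap = Inf) {
  structure(list(kind = "shifted_nbinom", shift = shift, size = size,
                 mu = mu, cap = cap), class = "dist_spec")
}

#' @rdname dist_shifted_nbinom
#' @export
dist_shifted_geometric <- function(p, cap = Inf) {
  structure(list(kind = "shifted_geometric", p = p, cap = cap),
            class = "dist_spec")
}

#' @rdname dist_shifted_nbinom
#' @export
dist_lognormal_int <- function(meanlog, sdlog, min = 2) {
  structure(list(kind = "lognormal_int", meanlog = meanlog, sdlog = sdlog,
                 min = min), class = "dist_spec")
}

#' @rdname dist_shifted_nbinom
#' @param spec a `dist_spec`.
#' @param n number of draws.
#' @export
draw_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  out <- switch(spec$kind,
    shifted_nbinom = spec$shift + stats::rnbinom(n, size = spec$size,
                                                 mu = spec$mu),
    shifted_geometric = 1 + stats::rgeom(n, prob = spec$p),
    lognormal_int = pmax(spec$min,
                         round(stats::rlnorm(n, spec$meanlog, spec$sdlog))),
    stop("unknown distribution kind: ", spec$kind, call. = FALSE)
  )
  if (!is.null(spec$cap)) out <- pmin(out, spec$cap)
  out
}

#' Generator configuration
#'
#' Assembles and validates the knobs of [generate_database()]. The
#' defaults (see [default_config()]) are calibrated to the published
#' census marginals; all distributions are swappable `dist_spec`s.
#'
#' @param n_reviews number of review records to emit (including
#'   protocols/withdrawn contaminants).
#' @param seed root integer seed. Each review derives its own
#'   pseudo-random substream from it, so adding reviews never perturbs
#'   earlier ones.
#' @param comparisons_per_review,outcomes_per_comparison,studies_per_plot
#'   `dist_spec`s for the branching factors; `studies_per_plot` must
#'   have support on 2, 3, ... (at least two genuine studies per plot
#'   before contamination).
#' @param sample_size `dist_spec` for participant sample size per study.
#' @param data_type_mixture named probabilities over `dichotomous`,
#'   `continuous`, `generic`, `oe_variance`; must sum to 1.
#' @param category_marginals list of probability tables for label
#'   assignment: `specialty` and `outcome` (named numeric vectors) and
#'   `intervention` (matrix over active categories by comparator kinds,
#'   `NA` for structurally empty cells). Categories are assigned
#'   independently across the three dimensions.
#' @param subgroup_split_rate probability that a plot presents its
#'   studies in 2-3 overlapping-capable subgroups rather than one.
#' @param phantom_rate probability a plot receives one appended phantom
#'   record.
#' @param duplicate_rate probability a multi-subgroup plot receives one
#'   within-plot duplicate of an earlier study.
#' @param protocol_rate,withdrawn_rate,methodology_rate probabilities a
#'   review record is a protocol, marked withdrawn, or belongs to the
#'   methodology group.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_reviews,
                             seed = 1L,
                             comparisons_per_review =
                               dist_shifted_geometric(0.61, cap = 23),
                             outcomes_per_comparison =
                               dist_shifted_nbinom(1, size = 0.44, mu = 4.15,
                                                   cap = 68),
                             studies_per_plot =
                               dist_shifted_nbinom(2, size = 0.37, mu = 2.85,
                                                   cap = 294),
                             sample_size =
                               dist_lognormal_int(log(91), 1.1586, min = 2),
                             data_type_mixture = c(
                               dichotomous = 0.66298, continuous = 0.29716,
                               generic = 0.02990, oe_variance = 0.00996),
                             category_marginals = default_category_marginals(),
                             subgroup_split_rate = 0.25,
                             phantom_rate = 0.1,
                             duplicate_rate = 0.05,
                             protocol_rate = 0.345,
                             withdrawn_rate = 0.01,
                             methodology_rate = 0.005) {
  cfg <- structure(
    list(n_reviews = as.integer(n_reviews), seed = as.integer(seed),
         comparisons_per_review = comparisons_per_review,
         outcomes_per_comparison = outcomes_per_comparison,
         studies_per_plot = studies_per_plot,
         sample_size = sample_size,
         data_type_mixture = data_type_mixture / sum(data_type_mixture),
         category_marginals = category_marginals,
         subgroup_split_rate = subgroup_split_rate,
         phantom_rate = phantom_rate,
         duplicate_rate = duplicate_rate,
         protocol_rate = protocol_rate,
         withdrawn_rate = withdrawn_rate,
         methodology_rate = methodology_rate),
    class = "generator_config"
  )
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (is.na(cfg$n_reviews) || cfg$n_reviews < 0)
    stop("n_reviews must be a non-negative integer", call. = FALSE)
  probs <- c(cfg$subgroup_split_rate, cfg$phantom_rate, cfg$duplicate_rate,
             cfg$protocol_rate, cfg$withdrawn_rate, cfg$methodology_rate)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    stop("rates must be probabilities in [0, 1]", call. = FALSE)
  mix <- cfg$data_type_mixture
  if (!setequal(names(mix), DATA_TYPES) || any(mix < 0) ||
      abs(sum(mix) - 1) > 1e-9)
    stop("data_type_mixture must be probabilities over the four data types summing to 1",
         call. = FALSE)
  for (nm in c("comparisons_per_review", "outcomes_per_comparison",
               "studies_per_plot", "sample_size")) {
    if (!inherits(cfg[[nm]], "dist_spec"))
      stop(nm, " must be a dist_spec", call. = FALSE)
  }
  sp <- cfg$studies_per_plot
  if (sp$kind == "shifted_nbinom" && sp$shift < 2)
    stop("studies_per_plot must have support on {2, 3, ...}", call. = FALSE)
  invisible(cfg)
}

#' Default label marginals from the published census
#'
#' Normalises the shipped reference tables ([reference_marginals()])
#' into sampling probabilities: specialty and outcome category marginals
#' and the joint (active intervention, comparator kind) cell
#' probabilities.
#'
#' @return A list with `specialty`, `outcome` (named probability
#'   vectors) and `intervention` (probability matrix, structurally empty
#'   cell `NA`).
#' @export
default_category_marginals <- function() {
  ref <- reference_marginals()
  list(
    specialty = stats::setNames(ref$specialty$count / sum(ref$specialty$count),
                                ref$specialty$category),
    outcome = stats::setNames(ref$outcome$count / sum(ref$outcome$count),
                              ref$outcome$category),
    intervention = ref$intervention / sum(ref$intervention, na.rm = TRUE)
  )
}

#' Calibrated default configuration
#'
#' The documented calibration of the generator to the published census
#' of a complete review-database issue: data-type mixture proportional
#' to the printed 14886 dichotomous / 6672 continuous / 895 mixed
#' meta-analyses (mixed split 3:1 between generic and O-E/variance as a
#' package assumption); study sample sizes log-normal with median 91 and
#' scale `(ln 210 - ln 44) / (2 * 0.6745) = 1.159` matched to the
#' printed quartiles 44/91/210; studies per plot a shifted negative
#' binomial matched to the printed quantiles 3/6/10/28; branching
#' factors matched to the printed per-review five-number summaries; and
#' label marginals proportional to the published category tables.
#'
#' @param n_reviews number of reviews (default 500).
#' @param seed root seed.
#' @param ... overrides passed on to [generator_config()].
#' @return A `generator_config`.
#' @export
default_config <- function(n_reviews = 500, seed = 1L, ...) {
  generator_config(n_reviews = n_reviews, seed = seed, ...)
}

#' Generate a synthetic review database
#'
#' Deterministically (given the seed) builds a synthetic
#' [sr_database()]: review records with status/specialty, comparisons
#' with intervention labels drawn from the joint cell marginals,
#' forest plots with data type, outcome category and at least two
#' genuine studies, per-study payloads consistent with the declared
#' data type, and then contamination applied last: a phantom
#' zero-pattern record appended to a plot with probability
#' `phantom_rate` (patterns exactly as [is_phantom_study()] defines
#' them) and, in multi-subgroup plots, a duplicate re-insertion of an
#' earlier study into a later subgroup with probability
#' `duplicate_rate`. Genuine draws that would collide with a phantom
#' pattern are nudged away from it, so the injected contamination is
#' exactly recoverable.
#'
#' @param config a [generator_config()].
#' @return A list with `db` (the emitted database) and `ground_truth`,
#'   a list holding `phantoms` and `duplicates` (data frames keying
#'   every injected row by plot and in-plot position, same shape as a
#'   curation report's `removed` tables) and `pre_contamination` counts
#'   at every hierarchy level.
#' @export
generate_database <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_reviews
  marg <- config$category_marginals
  cells <- which(!is.na(marg$intervention), arr.ind = TRUE)
  cell_probs <- marg$intervention[cells]
  actives <- rownames(marg$intervention)
  kinds <- colnames(marg$intervention)

  rv <- list(); cp <- list(); oc <- list(); st <- list()
  phantoms <- list(); duplicates <- list()
  pre <- c(reviews = 0L, comparisons = 0L, plots = 0L, studies = 0L)

  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, i))
    rid <- sprintf("R%04d", i)
    status <- sample(c("full", "protocol", "withdrawn"), 1,
                     prob = c(1 - config$protocol_rate - config$withdrawn_rate,
                              config$protocol_rate, config$withdrawn_rate))
    is_meth <- stats::runif(1) < config$methodology_rate
    specialty <- sample(names(marg$specialty), 1, prob = marg$specialty)
    rv[[i]] <- data.frame(
      review_id = rid,
      title = sprintf("Synthetic review %04d (%s)", i, specialty),
      review_group = if (is_meth) "Methodology Group"
                     else paste(specialty, "Group"),
      status = status, is_methodology_group = is_meth,
      specialty_label = specialty, stringsAsFactors = FALSE
    )
    pre["reviews"] <- pre["reviews"] + 1L

    n_comp <- draw_dist(config$comparisons_per_review, 1)
    for (j in seq_len(n_comp)) {
      cell <- sample(nrow(cells), 1, prob = cell_probs)
      active <- actives[cells[cell, 1]]
      kind <- kinds[cells[cell, 2]]
      comparator <- comparator_label_for(active, kind, actives)
      cid <- sprintf("C%02d", j)
      cp[[length(cp) + 1]] <- data.frame(
        review_id = rid, comparison_id = cid,
        name = paste(active, "vs", comparator),
        active_intervention_label = active, comparator_label = comparator,
        stringsAsFactors = FALSE
      )
      pre["comparisons"] <- pre["comparisons"] + 1L

      n_out <- draw_dist(config$outcomes_per_comparison, 1)
      for (k in seq_len(n_out)) {
        oid <- sprintf("O%02d", k)
        dt <- sample(DATA_TYPES, 1, prob = config$data_type_mixture)
        ocat <- sample(names(marg$outcome), 1, prob = marg$outcome)
        oc[[length(oc) + 1]] <- data.frame(
          review_id = rid, comparison_id = cid, outcome_id = oid,
          name = sprintf("%s, outcome %d", ocat, k), data_type = dt,
          totals_displayed = stats::runif(1) < 0.9,
          outcome_category_label = ocat, stringsAsFactors = FALSE
        )
        pre["plots"] <- pre["plots"] + 1L

        n_st <- draw_dist(config$studies_per_plot, 1)
        sizes <- draw_dist(config$sample_size, n_st)
        ids <- study_ids(n_st)
        split <- stats::runif(1) < config$subgroup_split_rate && n_st >= 3
        subgroups <- if (split) {
          n_sg <- sample(2:3, 1)
          sort(sample(paste("Subgroup", seq_len(n_sg)), n_st, replace = TRUE))
        } else rep("All studies", n_st)
        rows <- genuine_payloads(dt, n_st, sizes)
        rows <- cbind(
          data.frame(review_id = rid, comparison_id = cid, outcome_id = oid,
                     subgroup = subgroups, study_id = ids,
                     stringsAsFactors = FALSE),
          rows
        )
        pre["studies"] <- pre["studies"] + n_st

        # contamination: one duplicate re-insertion into a later subgroup
        if (split && stats::runif(1) < config$duplicate_rate) {
          sgs <- unique(rows$subgroup)
          if (length(sgs) >= 2) {
            src <- which(rows$subgroup == sgs[1])[1]
            dup <- rows[src, , drop = FALSE]
            dup$subgroup <- sgs[length(sgs)]
            rows <- rbind(rows, dup)
            duplicates[[length(duplicates) + 1]] <- data.frame(
              review_id = rid, comparison_id = cid, outcome_id = oid,
              subgroup = dup$subgroup, study_id = dup$study_id,
              position = nrow(rows), stringsAsFactors = FALSE
            )
          }
        }
        # contamination: one appended phantom record
        if (stats::runif(1) < config$phantom_rate) {
          ph <- phantom_payload(dt)
          ph_id <- sprintf("Listed %03d", n_st + 1)
          ph_row <- cbind(
            data.frame(review_id = rid, comparison_id = cid, outcome_id = oid,
                       subgroup = rows$subgroup[nrow(rows)], study_id = ph_id,
                       stringsAsFactors = FALSE),
            ph
          )
          rows <- rbind(rows, ph_row)
          phantoms[[length(phantoms) + 1]] <- data.frame(
            review_id = rid, comparison_id = cid, outcome_id = oid,
            subgroup = ph_row$subgroup, study_id = ph_id,
            position = nrow(rows), stringsAsFactors = FALSE
          )
        }
        st[[length(st) + 1]] <- rows
      }
    }
  }

  db <- sr_database(
    reviews = bind_rows_list(rv, empty_reviews()),
    comparisons = bind_rows_list(cp, empty_comparisons()),
    outcomes = bind_rows_list(oc, empty_outcomes()),
    studies = bind_rows_list(st, empty_studies()),
    issue_label = sprintf("synthetic issue (seed %d, %d reviews)",
                          config$seed, n),
    validate = FALSE
  )
  empty_keys <- data.frame(
    review_id = character(0), comparison_id = character(0),
    outcome_id = character(0), subgroup = character(0),
    study_id = character(0), position = integer(0), stringsAsFactors = FALSE
  )
  gt <- list(
    phantoms = bind_rows_list(phantoms, empty_keys),
    duplicates = bind_rows_list(duplicates, empty_keys),
    pre_contamination = pre
  )
  list(db = db, ground_truth = gt)
}

# deterministic per-review substream; kept below 2^31
substream_seed <- function(root, i) {
  (as.numeric(root) * 7919 + i * 104729) %% 2147483647
}

comparator_label_for <- function(active, kind, actives) {
  switch(kind,
    "Control" = "Control",
    "Placebo" = "Placebo",
    "Pharmacological" = "Pharmacological",
    "same-category non-pharm" = active,
    "different-category non-pharm" = {
      pool <- setdiff(actives, c(active, "Pharmacological"))
      sample(pool, 1)
    }
  )
}

SURNAMES <- c("Smith", "Jones", "Brown", "Wilson", "Taylor", "Evans", "Lee",
              "Chen", "Kumar", "Garcia", "Muller", "Rossi", "Silva", "Kim",
              "Novak", "Olsen", "Dubois", "Costa", "Popov", "Yamada")

study_ids <- function(n) {
  ids <- paste(sample(SURNAMES, n, replace = TRUE),
               sample(1980:2007, n, replace = TRUE))
  while (anyDuplicated(ids)) {
    d <- duplicated(ids)
    ids[d] <- paste0(ids[d], letters[seq_len(sum(d))])
  }
  ids
}

# payload rows for one plot; nudged off the phantom zero-patterns so
# injected contamination stays exactly identifiable
genuine_payloads <- function(data_type, n, sizes) {
  out <- as.data.frame(matrix(NA_real_, nrow = n, ncol = length(PAYLOAD_COLS),
                              dimnames = list(NULL, PAYLOAD_COLS)))
  if (data_type == "dichotomous") {
    n1 <- pmax(1, round(sizes * stats::runif(n, 0.4, 0.6)))
    n2 <- pmax(1, sizes - n1)
    p <- stats::rbeta(1, 2, 6)
    e1 <- stats::rbinom(n, n1, p)
    e2 <- stats::rbinom(n, n2, p)
    collide <- n1 == 1 & n2 == 1 & e1 == 0 & e2 == 0
    e1[collide] <- 1
    out$events_1 <- e1; out$total_1 <- n1
    out$events_2 <- e2; out$total_2 <- n2
  } else if (data_type == "continuous") {
    n1 <- pmax(1, round(sizes / 2)); n2 <- pmax(1, sizes - n1)
    out$n_1 <- n1; out$n_2 <- n2
    out$mean_1 <- stats::rnorm(n); out$mean_2 <- stats::rnorm(n)
    out$sd_1 <- stats::rlnorm(n, 0, 0.5); out$sd_2 <- stats::rlnorm(n, 0, 0.5)
  } else if (data_type == "generic") {
    out$estimate <- stats::rnorm(n, 0, 0.6)
    out$standard_error <- stats::rlnorm(n, -1, 0.5)
    out$total_n <- sizes
  } else {
    out$o_minus_e <- stats::rnorm(n, 0, sqrt(pmax(sizes / 8, 1)))
    out$variance <- pmax(sizes / 8, 0.5)
    out$total_n <- sizes
  }
  out
}

phantom_payload <- function(data_type) {
  out <- as.data.frame(matrix(NA_real_, nrow = 1, ncol = length(PAYLOAD_COLS),
                              dimnames = list(NULL, PAYLOAD_COLS)))
  if (data_type == "dichotomous") {
    out$events_1 <- 0; out$total_1 <- 1; out$events_2 <- 0; out$total_2 <- 1
  } else if (data_type == "continuous") {
    out$n_1 <- 1; out$n_2 <- 1
    out$mean_1 <- 0; out$mean_2 <- 0; out$sd_1 <- 0; out$sd_2 <- 0
  } else if (data_type == "generic") {
    out$estimate <- 0; out$standard_error <- 0; out$total_n <- 2
  } else {
    out$o_minus_e <- 0; out$variance <- 0; out$total_n <- 2
  }
  out
}
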