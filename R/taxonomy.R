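# Controlled vocabularies: 11 medical specialties, 17 intervention
# categories (15 active + Control and Placebo), 23 outcome categories
# with a priority order for multi-category outcomes, and the collapse
# maps used in stratified summaries (23 outcomes -> 11 groups; the four
# raw data types -> 3 data-type groups; intervention pairs -> 5 groups).

COLLAPSED5 <- c(
  "Pharm vs Control/Placebo",
  "Pharm vs Pharm",
  "Pharm vs Non-Pharm",
  "Non-Pharm vs Control/Placebo",
  "Non-Pharm vs Non-Pharm"
)

COMPARATOR_KINDS <- c(
  "Control", "Placebo", "Pharmacological",
  "same-category non-pharm", "different-category non-pharm"
)

#' Data-type grouping
#'
#' Maps the four raw payload types onto the three groups used in
#' summaries: dichotomous and continuous stand alone, while generic and
#' O-E/variance data are analysed together as mixed outcome data.
#'
#' @return Named character vector mapping data type to group.
#' @export
data_type_group <- function() {
  c(dichotomous = "Dichotomous", continuous = "Continuous",
    generic = "Mixed", oe_variance = "Mixed")
}

#' Specialty vocabulary
#'
#' @param categories character vector of exactly 11 unique specialty
#'   names.
#' @return Character vector of class `specialty_vocab`.
#' @export
specialty_vocab <- function(categories) {
  categories <- as.character(categories)
  if (length(categories) != 11 || anyDuplicated(categories))
    stop("specialty vocabulary must hold exactly 11 unique categories",
         call. = FALSE)
  structure(categories, class = "specialty_vocab")
}

#' Intervention vocabulary
#'
#' Fifteen "active" intervention categories plus the two control
#' categories. Exactly one active category (`pharmacological`) is the
#' pharmacological one; all other active categories count as
#' non-pharmacological in the five-way collapse.
#'
#' @param active character vector of exactly 15 unique active categories.
#' @param control character vector of exactly 2 control categories
#'   (default `c("Control", "Placebo")`).
#' @param pharmacological name of the pharmacological active category.
#' @return A list of class `intervention_vocab` with elements `active`,
#'   `control` and `pharmacological`.
#' @export
intervention_vocab <- function(active, control = c("Control", "Placebo"),
                               pharmacological = "Pharmacological") {
  active <- as.character(active); control <- as.character(control)
  if (length(active) != 15 || anyDuplicated(active))
    stop("intervention vocabulary needs exactly 15 unique active categories",
         call. = FALSE)
  if (length(control) != 2 || anyDuplicated(control))
    stop("intervention vocabulary needs exactly 2 control categories",
         call. = FALSE)
  if (length(intersect(active, control)))
    stop("active and control categories must not overlap", call. = FALSE)
  if (!pharmacological %in% active)
    stop("pharmacological category '", pharmacological,
         "' is not among the active categories", call. = FALSE)
  structure(list(active = active, control = control,
                 pharmacological = pharmacological),
            class = "intervention_vocab")
}

#' Outcome vocabulary with priority order
#'
#' Twenty-three outcome categories together with a complete priority
#' permutation: an outcome that could fall under several categories is
#' assigned the category highest on the priority list.
#'
#' @param categories character vector of exactly 23 unique category
#'   names.
#' @param priority_order permutation of `categories`, highest priority
#'   first; defaults to `categories` in the order given.
#' @return A list of class `outcome_vocab` with elements `categories`
#'   and `priority_order`.
#' @export
outcome_vocab <- function(categories, priority_order = categories) {
  categories <- as.character(categories)
  priority_order <- as.character(priority_order)
  if (length(categories) != 23 || anyDuplicated(categories))
    stop("outcome vocabulary needs exactly 23 unique categories", call. = FALSE)
  if (!setequal(priority_order, categories) ||
      length(priority_order) != length(categories))
    stop("priority_order must be a complete permutation of the 23 categories",
         call. = FALSE)
  structure(list(categories = categories, priority_order = priority_order),
            class = "outcome_vocab")
}

#' Load vocabularies from a configuration file
#'
#' Reads a YAML configuration holding the specialty, intervention and
#' outcome vocabularies, the outcome priority order and the 23-to-11
#' outcome collapse map. The package ships a documented default at
#' `system.file("extdata", "vocabulary.yaml", package = "srcensus")`;
#' users can copy and edit it (for instance to re-order outcome
#' priorities) without code changes.
#'
#' @param path configuration file; defaults to the shipped vocabulary.
#' @return A list of class `vocabularies` with elements `specialty`,
#'   `intervention`, `outcome`, `outcome_group11` (named character map)
#'   and `data_type_group`.
#' @export
default_vocabularies <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vocabulary.yaml", package = "srcensus")
  }
  cfg <- yaml::read_yaml(path)
  ov <- outcome_vocab(cfg$outcome_priority_order, cfg$outcome_priority_order)
  map <- unlist(cfg$outcome_group11)
  vocabularies(
    specialty = specialty_vocab(cfg$specialty),
    intervention = intervention_vocab(cfg$intervention_active,
                                      cfg$intervention_control),
    outcome = ov,
    outcome_group11 = map
  )
}

#' Bundle vocabularies
#'
#' @param specialty a [specialty_vocab()].
#' @param intervention an [intervention_vocab()].
#' @param outcome an [outcome_vocab()].
#' @param outcome_group11 named character vector mapping all 23 outcome
#'   categories onto the 11 summary groups (total and surjective).
#' @return A list of class `vocabularies`.
#' @export
vocabularies <- function(specialty, intervention, outcome, outcome_group11) {
  stopifnot(inherits(specialty, "specialty_vocab"),
            inherits(intervention, "intervention_vocab"),
            inherits(outcome, "outcome_vocab"))
  if (!setequal(names(outcome_group11), outcome$categories))
    stop("outcome_group11 must map exactly the 23 outcome categories",
         call. = FALSE)
  groups <- unique(unname(outcome_group11))
  if (length(groups) != 11)
    stop("outcome_group11 must be surjective onto 11 groups (got ",
         length(groups), ")", call. = FALSE)
  structure(
    list(specialty = specialty, intervention = intervention,
         outcome = outcome, outcome_group11 = outcome_group11,
         data_type_group = data_type_group()),
    class = "vocabularies"
  )
}

#' Resolve a multi-category outcome by priority
#'
#' An outcome caption that could fall under several categories is
#' assigned the candidate highest on the vocabulary's priority list.
#' The result does not depend on the order of the candidates.
#'
#' @param candidates non-empty character vector of outcome category
#'   names, all in the vocabulary.
#' @param vocab an [outcome_vocab()].
#' @return The winning category name.
#' @export
#' @examples
#' v <- default_vocabularies()$outcome
#' resolve_outcome_category(c("Pain", "Adverse events"), v)  # "Adverse events"
resolve_outcome_category <- function(candidates, vocab) {
  stopifnot(inherits(vocab, "outcome_vocab"))
  candidates <- unique(as.character(candidates))
  if (!length(candidates)) stop("empty candidate set", call. = FALSE)
  pos <- match(candidates, vocab$priority_order)
  if (anyNA(pos))
    stop("unknown outcome category: ",
         paste(candidates[is.na(pos)], collapse = ", "), call. = FALSE)
  vocab$priority_order[min(pos)]
}

#' Classify a pair-wise intervention comparison
#'
#' Assigns the comparator kind of the 15-by-5 intervention
#' cross-tabulation and the five-way collapsed grouping. The first
#' intervention of a comparison is the "active" intervention (always one
#' of the 15 active categories); the comparator may be Control, Placebo
#' or any active category. Comparator kinds are: `Control`, `Placebo`,
#' `Pharmacological` (a pharmacological comparator), `same-category
#' non-pharm` and `different-category non-pharm`. A pharmacological
#' active intervention can never have a same-category non-pharmacological
#' comparator (that cell is structurally empty).
#'
#' @param active active intervention category.
#' @param comparator comparator category (active category, `"Control"`
#'   or `"Placebo"`).
#' @param vocab an [intervention_vocab()].
#' @return A list of class `comparison_class` with elements
#'   `active_category`, `comparator_kind` and `collapsed5`.
#' @export
#' @examples
#' v <- default_vocabularies()$intervention
#' classify_comparison("Pharmacological", "Placebo", v)$collapsed5
#' classify_comparison("Surgical", "Surgical", v)$comparator_kind
classify_comparison <- function(active, comparator, vocab) {
  stopifnot(inherits(vocab, "intervention_vocab"))
  if (length(active) != 1 || !active %in% vocab$active)
    stop("unknown active intervention category: ", active, call. = FALSE)
  if (length(comparator) != 1 ||
      !comparator %in% c(vocab$active, vocab$control))
    stop("unknown comparator category: ", comparator, call. = FALSE)
  pharm <- vocab$pharmacological
  active_is_pharm <- active == pharm

  kind <- if (comparator %in% vocab$control) {
    comparator
  } else if (comparator == pharm) {
    "Pharmacological"
  } else if (comparator == active) {
    "same-category non-pharm"
  } else {
    "different-category non-pharm"
  }

  collapsed <- if (comparator %in% vocab$control) {
    if (active_is_pharm) "Pharm vs Control/Placebo" else "Non-Pharm vs Control/Placebo"
  } else if (active_is_pharm && comparator == pharm) {
    "Pharm vs Pharm"
  } else if (active_is_pharm || comparator == pharm) {
    "Pharm vs Non-Pharm"
  } else {
    "Non-Pharm vs Non-Pharm"
  }

  structure(
    list(active_category = active, comparator_kind = kind,
         collapsed5 = collapsed),
    class = "comparison_class"
  )
}

#' Collapse an outcome category onto the 11 summary groups
#'
#' @param category one of the 23 outcome categories.
#' @param map named character vector, as in
#'   `default_vocabularies()$outcome_group11`.
#' @return The summary group name.
#' @export
collapse_outcome_group <- function(category, map) {
  out <- unname(map[category])
  if (anyNA(out))
    stop("unknown outcome category: ",
         paste(category[is.na(out)], collapse = ", "), call. = FALSE)
  out
}

#' Check every label in a database against the vocabularies
#'
#' Verifies review specialty labels, comparison intervention labels and
#' forest-plot outcome category labels against the controlled
#' vocabularies. A label that is missing where the census needs one
#' (specialty on a review, active/comparator on a comparison, outcome
#' category on a plot) is reported as a violation, as is any label
#' outside its vocabulary.
#'
#' @param db an [sr_database()].
#' @param vocabs a [vocabularies()] bundle.
#' @return A data frame with columns `path`, `field` and `message`; zero
#'   rows when all labels validate.
#' @export
validate_labels <- function(db, vocabs = default_vocabularies()) {
  stopifnot(is_sr_database(db), inherits(vocabs, "vocabularies"))
  out <- list()
  add <- function(path, field, message) {
    out[[length(out) + 1]] <<- data.frame(
      path = path, field = field, message = message, stringsAsFactors = FALSE)
  }
  rv <- db$reviews
  for (i in seq_len(nrow(rv))) {
    lab <- rv$specialty_label[i]
    if (is.na(lab)) {
      add(rv$review_id[i], "specialty_label", "missing specialty label")
    } else if (!lab %in% vocabs$specialty) {
      add(rv$review_id[i], "specialty_label",
          sprintf("specialty '%s' not in the 11-category vocabulary", lab))
    }
  }
  iv <- vocabs$intervention
  cp <- db$comparisons
  for (i in seq_len(nrow(cp))) {
    path <- paste(cp$review_id[i], cp$comparison_id[i], sep = "/")
    act <- cp$active_intervention_label[i]
    cmp <- cp$comparator_label[i]
    if (is.na(act)) {
      add(path, "active_intervention_label", "missing active intervention label")
    } else if (!act %in% iv$active) {
      add(path, "active_intervention_label",
          sprintf("active intervention '%s' not an active category", act))
    }
    if (is.na(cmp)) {
      add(path, "comparator_label", "missing comparator label")
    } else if (!cmp %in% c(iv$active, iv$control)) {
      add(path, "comparator_label",
          sprintf("comparator '%s' not in the intervention vocabulary", cmp))
    }
  }
  oc <- db$outcomes
  for (i in seq_len(nrow(oc))) {
    lab <- oc$outcome_category_label[i]
    path <- key_path(oc[i, ])
    if (is.na(lab)) {
      add(path, "outcome_category_label", "missing outcome category label")
    } else if (!lab %in% vocabs$outcome$categories) {
      add(path, "outcome_category_label",
          sprintf("outcome category '%s' not in the 23-category vocabulary", lab))
    }
  }
  if (!length(out)) {
    return(data.frame(path = character(0), field = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
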