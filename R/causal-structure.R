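#' Component-cause categories
#'
#' The four evolutionary categories of component causes: early-onset genetic
#' effects (`EOGE`), late-onset genetic effects (`LOGE`), evolutionarily
#' conserved environmental factors (`ECEF`) and evolutionarily recent
#' environmental factors (`EREF`). Genetic effects are early or late according
#' to whether they express before or after the earliest age of reproduction in
#' the population; environmental factors are conserved or recent according to
#' whether adaptation to them has had time to occur.
#'
#' @return Character vector of the four category codes.
#' @export
component_categories <- function() c("ECEF", "EOGE", "EREF", "LOGE")

#' Build a component cause
#'
#' A component cause is a genetic or environmental factor that expresses its
#' necessary causal role at a random age, following a time-to-event law.
#'
#' @param id Identifier, unique within a system.
#' @param category One of [component_categories()].
#' @param timing An `ebmc_dist` giving the age (years) of expression.
#' @return A `component_cause` object.
#' @export
component_cause <- function(id, category, timing) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            inherits(timing, "ebmc_dist"))
  category <- match.arg(category, component_categories())
  structure(list(id = id, category = category, timing = timing),
            class = "component_cause")
}

#' Build a sufficient cause
#'
#' A sufficient cause is a minimal set of component causes that jointly
#' produce the outcome; it completes at the *maximum* of its components'
#' expression ages. A component may belong to several sufficient causes —
#' sharing is legal and is the mechanism that induces dependence between
#' causes.
#'
#' @param id Identifier, unique within a system.
#' @param components Non-empty character vector of component-cause ids.
#' @return A `sufficient_cause` object.
#' @export
sufficient_cause <- function(id, components) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(components), length(components) >= 1L)
  structure(list(id = id, components = unique(components)),
            class = "sufficient_cause")
}

#' Build a causal system
#'
#' Bundles component causes and sufficient causes with the earliest age of
#' reproduction in the population (the lower terminus of the aging phase,
#' about 10 years in humans). The population-level outcome occurs at the
#' *minimum* completion age over the sufficient causes.
#'
#' @param components List of [component_cause()] objects.
#' @param sufficient_causes List of [sufficient_cause()] objects.
#' @param earliest_reproduction_age Age in years (`> 0`), default 10.
#' @return A `causal_system` object with tibble views `$components` and
#'   `$sufficient_causes`.
#' @seealso [validate_system()], [system_incidence_survival()],
#'   [simulate_first_event()]
#' @export
causal_system <- function(components, sufficient_causes,
                          earliest_reproduction_age = 10) {
  stopifnot(length(components) >= 1L, length(sufficient_causes) >= 1L,
            is.numeric(earliest_reproduction_age),
            earliest_reproduction_age > 0)
  stopifnot(all(vapply(components, inherits, logical(1), "component_cause")),
            all(vapply(sufficient_causes, inherits, logical(1), "sufficient_cause")))
  comp_tbl <- tibble::tibble(
    id = vapply(components, `[[`, character(1), "id"),
    category = vapply(components, `[[`, character(1), "category"),
    timing = lapply(components, `[[`, "timing")
  )
  sc_tbl <- tibble::tibble(
    id = vapply(sufficient_causes, `[[`, character(1), "id"),
    components = lapply(sufficient_causes, `[[`, "components")
  )
  structure(list(components = comp_tbl, sufficient_causes = sc_tbl,
                 earliest_reproduction_age = earliest_reproduction_age),
            class = "causal_system")
}

#' @export
print.causal_system <- function(x, ...) {
  cat(sprintf("<causal_system> %d components, %d sufficient causes, terminus %g y\n",
              nrow(x$components), nrow(x$sufficient_causes),
              x$earliest_reproduction_age))
  census <- system_type_census(x)
  cat("sufficient-cause category sets:\n")
  print(census, n = Inf)
  invisible(x)
}

# category set of each sufficient cause, as a sorted "+"-joined label
cause_category_sets <- function(system) {
  cat_of <- stats::setNames(system$components$category, system$components$id)
  lapply(system$sufficient_causes$components,
         function(ids) sort(unique(unname(cat_of[ids]))))
}

#' Census of sufficient-cause category subsets in a system
#'
#' @param system A [causal_system()].
#' @return Tibble with `categories` label, `molding` class and `n` causes.
#' @export
system_type_census <- function(system) {
  sets <- cause_category_sets(system)
  tibble::tibble(categories = vapply(sets, paste, character(1), collapse = "+")) |>
    dplyr::count(.data$categories, name = "n") |>
    dplyr::mutate(molding = vapply(strsplit(.data$categories, "\\+"),
                                   classify_molding, character(1)))
}

#' Classify a sufficient cause by its component-cause categories
#'
#' A sufficient cause whose categories are contained in `{EOGE, ECEF}`
#' expresses (by definition or assumption) before the earliest age of
#' reproduction and is `excluded` from the aging phase. Among the rest, a
#' cause containing `EREF` has *not* been molded by the declining force of
#' natural selection (`not_molded`, Weibull domain); a cause containing
#' `LOGE` without `EREF` has (`molded`, Gompertz domain).
#'
#' @param categories Non-empty character vector of category codes (a set;
#'   duplicates are ignored, so multiplicity never changes the class).
#' @return One of `"molded"`, `"not_molded"`, `"excluded"`.
#' @examples
#' classify_molding("LOGE")             # molded
#' classify_molding(c("LOGE", "EREF"))  # not_molded
#' classify_molding(c("EOGE", "ECEF"))  # excluded
#' @export
classify_molding <- function(categories) {
  if (length(categories) == 0L) stop("`categories` must be non-empty", call. = FALSE)
  categories <- unique(categories)
  bad <- setdiff(categories, component_categories())
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (all(categories %in% c("EOGE", "ECEF"))) return("excluded")
  if ("EREF" %in% categories) return("not_molded")
  "molded"  # LOGE present, EREF absent
}

#' Enumerate the sufficient-cause types
#'
#' The four component-cause categories combine into 15 types of sufficient
#' causes (non-empty category subsets). Types containing only `EOGE`/`ECEF`
#' express before the earliest age of reproduction and are not retained for
#' the aging phase, leaving 12 retained types: 4 molded and 8 not molded.
#'
#' @return Tibble with one row per non-empty subset, ordered
#'   lexicographically by the sorted category label: `categories` (list
#'   column), `label`, `retained`, `molding`.
#' @examples
#' types <- enumerate_cause_types()
#' nrow(types)            # 15
#' sum(types$retained)    # 12
#' @export
enumerate_cause_types <- function() {
  cats <- component_categories()
  subsets <- unlist(lapply(seq_along(cats), function(k) {
    combn(cats, k, simplify = FALSE)
  }), recursive = FALSE)
  labels <- vapply(subsets, paste, character(1), collapse = "+")
  ord <- order(labels)
  tibble::tibble(
    categories = subsets[ord],
    label = labels[ord],
    molding = vapply(subsets[ord], classify_molding, character(1))
  ) |>
    dplyr::mutate(retained = .data$molding != "excluded") |>
    dplyr::select("categories", "label", "retained", "molding")
}

#' Validate a causal system
#'
#' Report-style validation: checks id uniqueness, dangling component
#' references, the terminus constraint and unimodality of late-onset genetic
#' timing laws, and flags excluded-type sufficient causes (these are dropped
#' from incidence computations downstream, with a warning, but remain legal
#' in the data model). Never mutates the system.
#'
#' @param system A [causal_system()].
#' @return An `ebmc_validation` list: `ok` (no errors) and `messages`, a
#'   tibble with columns `level` (`"error"`/`"warning"`) and `message`.
#' @export
validate_system <- function(system) {
  stopifnot(inherits(system, "causal_system"))
  msgs <- list()
  note <- function(level, msg) {
    msgs[[length(msgs) + 1L]] <<- tibble::tibble(level = level, message = msg)
  }
  comp <- system$components
  sc <- system$sufficient_causes
  era <- system$earliest_reproduction_age

  if (anyDuplicated(comp$id)) note("error", "duplicate component ids")
  if (anyDuplicated(sc$id)) note("error", "duplicate sufficient-cause ids")
  for (i in seq_len(nrow(sc))) {
    missing <- setdiff(sc$components[[i]], comp$id)
    if (length(missing)) {
      note("error", sprintf("sufficient cause '%s' references missing component(s): %s",
                            sc$id[i], paste(missing, collapse = ", ")))
    }
  }
  for (i in seq_len(nrow(comp))) {
    d <- comp$timing[[i]]
    if (comp$category[i] == "LOGE") {
      if (dist_quantile(d, 0) < era - 1e-9) {
        note("error", sprintf("LOGE component '%s' has support below the earliest reproduction age (%g y)",
                              comp$id[i], era))
      }
      uni <- tryCatch(is_unimodal(d), error = function(e) NA)
      if (isFALSE(uni)) {
        note("error", sprintf("LOGE component '%s' timing density is not unimodal",
                              comp$id[i]))
      }
    }
  }
  dangling <- vapply(seq_len(nrow(sc)), function(i) {
    length(setdiff(sc$components[[i]], comp$id)) > 0
  }, logical(1))
  sets <- cause_category_sets(system)
  for (i in seq_len(nrow(sc))) {
    if (dangling[i]) next
    if (classify_molding(sets[[i]]) == "excluded") {
      note("warning", sprintf("sufficient cause '%s' is an excluded type (%s): it expresses before the aging phase and is skipped in incidence computations",
                              sc$id[i], paste(sets[[i]], collapse = "+")))
    }
  }
  messages <- if (length(msgs)) dplyr::bind_rows(msgs) else
    tibble::tibble(level = character(), message = character())
  structure(list(ok = !any(messages$level == "error"), messages = messages),
            class = "ebmc_validation")
}

#' @export
print.ebmc_validation <- function(x, ...) {
  cat(sprintf("<ebmc_validation> ok = %s\n", x$ok))
  if (nrow(x$messages)) {
    for (i in seq_len(nrow(x$messages))) {
      cat(sprintf("  [%s] %s\n", x$messages$level[i], x$messages$message[i]))
    }
  }
  invisible(x)
}
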