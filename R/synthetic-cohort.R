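# Seeded generators for causal systems and individual-level cohorts, so every
# other module is testable without external data. The cohort generator
# emulates a long-running mortality follow-up: right-censored ages at death
# from a parametric source (or a simulated causal system), optional
# extrinsic deaths from a constant hazard, and administrative censoring.

#' Generate a random causal system
#'
#' Draws component causes with category-appropriate timing laws and assembles
#' sufficient causes that may share components:
#' * `LOGE`: shifted lognormal above the earliest reproduction age (unimodal);
#' * `EREF`: threshold-exposure law (random onset, accrual rate, threshold);
#' * `EOGE`: shifted gamma with early support;
#' * `ECEF`: early uniform-type (regularly-varying) law.
#'
#' Each sufficient cause draws its size from `size_probs`, then fills slots
#' by reusing an existing component with probability `share_prob` (the
#' dependence mechanism), else creating a new one with category frequencies
#' proportional to `n_per_category`. With `aging_phase = TRUE` (default) the
#' first slot of every cause is a late-expressing component (`LOGE` or
#' `EREF`), so every generated cause is a retained type.
#'
#' @param n_per_category Named counts for the initial component pool; also
#'   sets the category frequencies for newly created components. Categories
#'   with count 0 never appear (e.g. drop `EREF` for a molded-only system).
#' @param n_sufficient Number of sufficient causes (`>= 1`).
#' @param size_probs Probabilities for 1, 2, 3, ... components per cause.
#' @param share_prob Probability of reusing an existing component per slot.
#' @param aging_phase Force every cause to contain a `LOGE` or `EREF`.
#' @param earliest_reproduction_age Lower terminus (years).
#' @param seed Optional integer seed.
#' @return A [causal_system()]; the category-subset census is attached as
#'   attribute `census`.
#' @export
generate_system <- function(n_per_category = c(EOGE = 2, LOGE = 3, ECEF = 2, EREF = 2),
                            n_sufficient = 5,
                            size_probs = c(0.2, 0.4, 0.3, 0.1),
                            share_prob = 0.3,
                            aging_phase = TRUE,
                            earliest_reproduction_age = 10,
                            seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_system(
      n_per_category, n_sufficient, size_probs, share_prob, aging_phase,
      earliest_reproduction_age)))
  }
  stopifnot(n_sufficient >= 1, share_prob >= 0, share_prob <= 1,
            all(names(n_per_category) %in% component_categories()))
  n_per_category <- n_per_category[n_per_category > 0]
  if (!length(n_per_category)) stop("no categories enabled", call. = FALSE)
  era <- earliest_reproduction_age
  late_cats <- intersect(names(n_per_category), c("LOGE", "EREF"))
  if (aging_phase && !length(late_cats)) {
    stop("aging-phase systems need LOGE and/or EREF components enabled",
         call. = FALSE)
  }

  new_timing <- function(category) {
    switch(category,
      LOGE = dist_lognormal(meanlog = stats::runif(1, 3.2, 4.2),
                            sdlog = stats::runif(1, 0.2, 0.5), terminus = era),
      EREF = dist_threshold(
        onset = dist_lognormal(log(stats::runif(1, 15, 25)), 0.3, terminus = 0),
        rate = dist_gamma(shape = 4, rate = 4, terminus = 0),
        threshold = dist_lognormal(log(stats::runif(1, 25, 45)), 0.5, terminus = 0)),
      EOGE = dist_gamma(shape = 2, rate = stats::runif(1, 0.5, 1.5), terminus = 0),
      ECEF = dist_regvar(c = 1 / stats::runif(1, 2, 8), rho = 1, terminus = 0),
      stop("unknown category ", category))
  }

  pool <- list()  # component_cause objects, by id
  counter <- stats::setNames(rep(0L, length(n_per_category)), names(n_per_category))
  add_component <- function(category) {
    counter[category] <<- counter[category] + 1L
    id <- sprintf("%s_%d", category, counter[category])
    pool[[id]] <<- component_cause(id, category, new_timing(category))
    id
  }
  for (cat in names(n_per_category)) {
    for (i in seq_len(n_per_category[[cat]])) add_component(cat)
  }
  cat_freq <- n_per_category / sum(n_per_category)
  pick_new <- function(cats) {
    pr <- cat_freq[cats] / sum(cat_freq[cats])
    sample(cats, 1, prob = pr)
  }

  causes <- vector("list", n_sufficient)
  for (k in seq_len(n_sufficient)) {
    size <- sample.int(length(size_probs), 1, prob = size_probs)
    ids <- character(0)
    for (slot in seq_len(size)) {
      force_late <- aging_phase && slot == 1L
      cand_cats <- if (force_late) late_cats else names(n_per_category)
      reuse_pool <- names(pool)[vapply(pool, function(cc) {
        cc$category %in% cand_cats
      }, logical(1))]
      reuse_pool <- setdiff(reuse_pool, ids)
      if (length(reuse_pool) && stats::runif(1) < share_prob) {
        ids <- c(ids, sample(reuse_pool, 1))
      } else {
        ids <- c(ids, add_component(pick_new(cand_cats)))
      }
    }
    causes[[k]] <- sufficient_cause(sprintf("sc_%03d", k), ids)
  }
  sys <- causal_system(unname(pool), causes, earliest_reproduction_age = era)
  attr(sys, "census") <- system_type_census(sys)
  sys
}

#' Generate a right-censored cohort
#'
#' Event ages come from [simulate_first_event()] (causal-system source) or
#' labelled mixture sampling (parametric source). An optional independent
#' extrinsic death age is drawn from a constant hazard whose clock starts at
#' the source terminus (so intrinsic and extrinsic exponential risks compete
#' on the same origin). The observed time is the minimum of the intrinsic
#' event, extrinsic death, and censoring age, with `event` indicator and a
#' `label` in `intrinsic` / `extrinsic` / `censored`; `cause` carries the
#' sufficient-cause id or mixture component of intrinsic events so
#' intrinsic-only analyses can filter on it.
#'
#' With `entry_range`, individuals enter observation at an age drawn
#' uniformly from the range and their intrinsic age is drawn conditionally on
#' exceeding the entry age (left truncation); administrative censoring then
#' happens at `entry + followup_years`. The default emulation of a long
#' mortality follow-up is `entry_range = NULL` (all observed from the
#' terminus) with a fixed administrative censoring age.
#'
#' @param source A [causal_system()], [mixture_params()] or any `ebmc_dist`.
#' @param n Number of individuals.
#' @param admin_censor_age Administrative censoring age (years), or `NULL`.
#' @param censor_rate Constant random-censoring hazard from the terminus, or
#'   `NULL`.
#' @param extrinsic_hazard Constant extrinsic death hazard (Makeham-type
#'   additive constant), or `NULL` for none.
#' @param entry_range Length-2 vector of entry ages for left-truncated
#'   designs, or `NULL`.
#' @param followup_years Follow-up duration after entry when `entry_range`
#'   is used (default 43).
#' @param seed Optional integer seed.
#' @return Tibble `time`, `event`, `entry`, `label`, `cause` with class
#'   `censored_sample` columns compatible with [fit_mortality()].
#' @export
generate_cohort <- function(source, n, admin_censor_age = NULL,
                            censor_rate = NULL, extrinsic_hazard = NULL,
                            entry_range = NULL, followup_years = 43,
                            seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_cohort(
      source, n, admin_censor_age, censor_rate, extrinsic_hazard,
      entry_range, followup_years)))
  }
  stopifnot(n >= 1)
  if (inherits(source, "causal_system")) {
    a <- source$earliest_reproduction_age
  } else if (inherits(source, "ebmc_dist")) {
    a <- dist_terminus(source)
  } else stop("`source` must be a causal_system or an ebmc_dist", call. = FALSE)

  entry <- if (is.null(entry_range)) rep(a, n) else
    stats::runif(n, entry_range[1], entry_range[2])
  if (any(entry < a)) stop("entry ages below the source terminus", call. = FALSE)

  if (inherits(source, "causal_system")) {
    if (!is.null(entry_range)) {
      stop("left-truncated entry is only supported for parametric sources",
           call. = FALSE)
    }
    sim <- simulate_first_event(source, n)
    intrinsic <- sim$event_age
    cause <- sim$cause_id
  } else if (inherits(source, "mixture_params")) {
    if (is.null(entry_range)) {
      # latent component labels carried through directly
      draw <- sample_mixture(source, n)
      intrinsic <- draw$age
      cause <- draw$component
    } else {
      # conditional-on-entry inverse transform Q(F(entry) + U * S(entry)),
      # component attributed by its posterior probability given the age
      Fe <- dist_cdf(source, entry)
      u <- stats::runif(n)
      ages <- dist_quantile(source, pmin(Fe + u * (1 - Fe), 1 - 1e-15))
      intrinsic <- ages
      cause <- component_of_mixture(source, ages)
    }
  } else {
    Fe <- dist_cdf(source, entry)
    u <- stats::runif(n)
    intrinsic <- dist_quantile(source, pmin(Fe + u * (1 - Fe), 1 - 1e-15))
    cause <- rep(NA_character_, n)
  }

  extrinsic <- if (is.null(extrinsic_hazard)) rep(Inf, n) else
    pmax(entry, a) + stats::rexp(n, extrinsic_hazard)
  censor <- rep(Inf, n)
  if (!is.null(admin_censor_age)) censor <- pmin(censor, admin_censor_age)
  if (!is.null(censor_rate)) censor <- pmin(censor, a + stats::rexp(n, censor_rate))
  if (!is.null(entry_range)) censor <- pmin(censor, entry + followup_years)

  time <- pmin(intrinsic, extrinsic, censor)
  label <- dplyr::case_when(
    time == intrinsic ~ "intrinsic",
    time == extrinsic ~ "extrinsic",
    TRUE ~ "censored"
  )
  tibble::tibble(
    time = time,
    event = as.integer(label != "censored"),
    entry = entry,
    label = label,
    cause = ifelse(label == "intrinsic", cause, NA_character_)
  )
}

# posterior-free component attribution used when the mixture itself drew the
# ages: re-derives the label from the latent draw structure
component_of_mixture <- function(mp, ages) {
  # draws in generate_cohort come conditionally; attribute by posterior draw
  p <- mp$params$p
  fg <- p * dist_pdf(mp$params$gompertz, ages)
  fw <- (1 - p) * dist_pdf(mp$params$weibull, ages)
  post <- fg / pmax(fg + fw, .Machine$double.xmin)
  ifelse(stats::runif(length(ages)) < post, "gompertz", "weibull")
}
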