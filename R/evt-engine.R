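# Exact extreme-value constructions over causal systems, Monte-Carlo
# simulation honouring shared components, and convergence experiments toward
# the Gompertz / Weibull limits for minima.

#' Exact max / min constructions
#'
#' `max_cdf()` returns the cdf of the maximum of independent random variables
#' with the given cdfs (`x -> prod F_i(x)`): the completion age of a
#' sufficient cause is the maximum of its components' expression ages.
#' `min_survival()` returns the survival function of the minimum of
#' independent random variables with the given survival functions
#' (`x -> prod S_j(x)`): the population first-event age is the minimum over
#' sufficient causes.
#'
#' @param component_cdfs Non-empty list of vectorised cdf functions.
#' @param cause_survivals Non-empty list of vectorised survival functions.
#' @return A vectorised function of age.
#' @examples
#' unif <- function(x) pmin(pmax(x, 0), 1)
#' max_cdf(list(unif, unif))(0.5)  # 0.25
#' @export
max_cdf <- function(component_cdfs) {
  if (!is.list(component_cdfs) || length(component_cdfs) == 0L) {
    stop("`component_cdfs` must be a non-empty list of functions", call. = FALSE)
  }
  stopifnot(all(vapply(component_cdfs, is.function, logical(1))))
  function(x) {
    Reduce(`*`, lapply(component_cdfs, function(f) f(x)))
  }
}

#' @rdname max_cdf
#' @export
min_survival <- function(cause_survivals) {
  if (!is.list(cause_survivals) || length(cause_survivals) == 0L) {
    stop("`cause_survivals` must be a non-empty list of functions", call. = FALSE)
  }
  stopifnot(all(vapply(cause_survivals, is.function, logical(1))))
  function(x) {
    Reduce(`*`, lapply(cause_survivals, function(f) f(x)))
  }
}

# retained (non-excluded) sufficient causes of a system, with their component
# row indices; warns about dropped excluded types
retained_causes <- function(system, warn = TRUE) {
  sets <- cause_category_sets(system)
  classes <- vapply(sets, classify_molding, character(1))
  excluded <- classes == "excluded"
  if (warn && any(excluded)) {
    warning(sum(excluded), " excluded-type sufficient cause(s) dropped from the incidence computation",
            call. = FALSE)
  }
  idx <- which(!excluded)
  list(
    idx = idx,
    n_excluded = sum(excluded),
    component_rows = lapply(idx, function(i) {
      match(system$sufficient_causes$components[[i]], system$components$id)
    })
  )
}

#' Population incidence survival of a causal system (analytic path)
#'
#' Builds the exact product-form survival function for the first event in the
#' population: each retained sufficient cause's survival is
#' `1 - prod F_component`, and the population survival is the product over
#' causes, left-truncated at the earliest reproduction age (renormalised so
#' `S(terminus) = 1`). Excluded-type causes are dropped (counted in the
#' metadata).
#'
#' This analytic path assumes the sufficient causes are independent; when
#' components are shared between causes that assumption is wrong by
#' construction, and the dependence is honoured only by
#' [simulate_first_event()]. The returned metadata records whether sharing
#' was ignored.
#'
#' @param system A [causal_system()] that passes [validate_system()].
#' @return An `ebmc_incidence` list: `survival` (vectorised function),
#'   `n_causes_used`, `n_excluded`, `terminus`, `shared_components_ignored`.
#' @export
system_incidence_survival <- function(system) {
  v <- validate_system(system)
  if (!v$ok) {
    stop("system fails validation:\n",
         paste(v$messages$message[v$messages$level == "error"], collapse = "\n"),
         call. = FALSE)
  }
  rc <- retained_causes(system)
  if (length(rc$idx) == 0L) {
    stop("no retained sufficient causes: nothing contributes to the aging phase",
         call. = FALSE)
  }
  timing <- system$components$timing
  cause_survs <- lapply(rc$component_rows, function(rows) {
    cdfs <- lapply(timing[rows], function(d) function(x) dist_cdf(d, x))
    Fmax <- max_cdf(cdfs)
    function(x) 1 - Fmax(x)
  })
  S_raw <- min_survival(cause_survs)
  a0 <- system$earliest_reproduction_age
  S0 <- S_raw(a0)
  if (S0 <= 0) stop("population survival is 0 at the terminus; cannot left-truncate",
                    call. = FALSE)
  n_comp_per_cause <- lengths(rc$component_rows)
  all_rows <- unlist(rc$component_rows)
  shared <- anyDuplicated(all_rows) > 0
  structure(list(
    survival = function(x) ifelse(x <= a0, 1, pmin(1, S_raw(x) / S0)),
    n_causes_used = length(rc$idx),
    n_excluded = rc$n_excluded,
    terminus = a0,
    shared_components_ignored = shared
  ), class = "ebmc_incidence")
}

#' @export
print.ebmc_incidence <- function(x, ...) {
  cat(sprintf("<ebmc_incidence> %d sufficient cause(s) used, %d excluded, terminus %g y\n",
              x$n_causes_used, x$n_excluded, x$terminus))
  if (x$shared_components_ignored) {
    cat("note: components are shared between causes; this analytic product ignores the induced dependence (use simulate_first_event())\n")
  }
  invisible(x)
}

#' Evaluate an incidence survival on an age grid
#'
#' @param x An `ebmc_incidence`.
#' @param ages Age grid; defaults to 1000 points over 100 years past the
#'   terminus.
#' @param ... Unused.
#' @return Tibble with `age`, `survival` and a finite-difference `hazard`.
#' @method tidy ebmc_incidence
#' @export
tidy.ebmc_incidence <- function(x, ages = NULL, ...) {
  if (is.null(ages)) ages <- seq(x$terminus, x$terminus + 100, length.out = 1000)
  S <- x$survival(ages)
  h <- -c(diff(log(pmax(S, 1e-300))) / diff(ages), NA_real_)
  tibble::tibble(age = ages, survival = S, hazard = h)
}

#' Simulate first-event ages honouring shared components
#'
#' Per individual, each component cause is sampled exactly once; a component
#' shared by several sufficient causes shares its draw across them (this
#' realises the dependence that the analytic product ignores). Each retained
#' cause completes at the maximum over its components, the event is the
#' minimum over causes, and simultaneous completions are attributed to the
#' smallest cause id (the tie fraction is reported as an attribute).
#' Individuals whose event age falls at or below the earliest reproduction
#' age are resampled and counted (`n_resampled` attribute): the simulated law
#' is conditional on the event occurring in the aging phase, matching the
#' left truncation of the analytic path.
#'
#' @param system A [causal_system()].
#' @param n Number of individuals (`>= 1`).
#' @param seed Optional integer seed (reproducible draws).
#' @return Tibble with columns `individual`, `event_age`, `cause_id`;
#'   attributes `tie_fraction` and `n_resampled`.
#' @export
simulate_first_event <- function(system, n, seed = NULL) {
  stopifnot(inherits(system, "causal_system"), n >= 1)
  if (!is.null(seed)) return(withr::with_seed(seed, simulate_first_event(system, n)))
  rc <- retained_causes(system, warn = FALSE)
  if (length(rc$idx) == 0L) stop("no retained sufficient causes", call. = FALSE)
  a0 <- system$earliest_reproduction_age
  comp_rows <- sort(unique(unlist(rc$component_rows)))
  timing <- system$components$timing
  # order causes by id so ties resolve to the smallest cause id
  cause_ids <- system$sufficient_causes$id[rc$idx]
  ord <- order(cause_ids)
  cause_rows <- rc$component_rows[ord]
  cause_ids <- cause_ids[ord]

  draw_events <- function(m) {
    comp_draws <- matrix(NA_real_, nrow = m, ncol = nrow(system$components))
    for (j in comp_rows) comp_draws[, j] <- dist_draw(timing[[j]], m)
    completion <- vapply(cause_rows, function(rows) {
      if (length(rows) == 1L) comp_draws[, rows] else
        do.call(pmax, lapply(rows, function(j) comp_draws[, j]))
    }, numeric(m))
    completion <- matrix(completion, nrow = m)
    event <- do.call(pmin, lapply(seq_len(ncol(completion)),
                                  function(k) completion[, k]))
    which_cause <- max.col(-completion, ties.method = "first")
    n_at_min <- rowSums(completion <= event + 0)
    list(event = event, cause = cause_ids[which_cause], ties = n_at_min > 1L)
  }

  res <- draw_events(n)
  n_resampled <- 0L
  for (iter in seq_len(100)) {
    bad <- which(res$event <= a0)
    if (!length(bad)) break
    n_resampled <- n_resampled + length(bad)
    redo <- draw_events(length(bad))
    res$event[bad] <- redo$event
    res$cause[bad] <- redo$cause
    res$ties[bad] <- redo$ties
  }
  if (any(res$event <= a0)) {
    stop("events keep falling below the earliest reproduction age; system support is inconsistent with the aging phase",
         call. = FALSE)
  }
  out <- tibble::tibble(individual = seq_len(n), event_age = res$event,
                        cause_id = res$cause)
  attr(out, "tie_fraction") <- mean(res$ties)
  attr(out, "n_resampled") <- n_resampled
  out
}

#' Convergence of simulated minima to the predicted limit family
#'
#' Simulates `n_reps` minima of `n_causes` independent draws from an initial
#' law (by exact inverse transform of the minimum distribution,
#' `Q(1 - (1 - U)^(1/n))`), classifies the initial law's minimum domain of
#' attraction with [classify_domain()], fits the predicted limit family to
#' the minima by maximum likelihood, and reports the Kolmogorov-Smirnov
#' distance between the empirical minima and the fitted limit. Flat initial
#' laws should approach a Gompertz limit and regularly-varying laws a Weibull
#' limit; the fitted-limit KS distance is the operative accuracy measure.
#'
#' @param initial_dist An `ebmc_dist` with a finite lower terminus.
#' @param n_causes Number of draws per minimum (`>= 1`).
#' @param n_reps Number of simulated minima (`>= 100`).
#' @param seed Optional integer seed.
#' @return List with `domain_predicted`, `fitted_limit` (an [ebmc_fit()]
#'   result, or a list of two fits when the domain is undetermined),
#'   `ks_distance`, `n_causes`, `n_reps`.
#' @export
convergence_to_limit <- function(initial_dist, n_causes, n_reps, seed = NULL) {
  stopifnot(inherits(initial_dist, "ebmc_dist"), n_causes >= 1, n_reps >= 100)
  if (!is.null(seed)) {
    return(withr::with_seed(seed,
      convergence_to_limit(initial_dist, n_causes, n_reps)))
  }
  u <- stats::runif(n_reps)
  minima <- dist_quantile(initial_dist, 1 - (1 - u)^(1 / n_causes))
  a <- dist_terminus(initial_dist)
  dom <- classify_domain(initial_dist)
  dat <- tibble::tibble(time = minima, event = 1L)
  fit_one <- function(family) {
    fit_mortality(dat, family = family, terminus = a, n_starts = 5, seed = 1L)
  }
  if (dom$domain == "gompertz_domain") {
    fit <- fit_one("gompertz")
    ks <- ks_distance(minima, function(x) dist_cdf(fit$dist, x))
  } else if (dom$domain == "weibull_domain") {
    fit <- fit_one("weibull")
    ks <- ks_distance(minima, function(x) dist_cdf(fit$dist, x))
  } else {
    fit <- list(gompertz = fit_one("gompertz"), weibull = fit_one("weibull"))
    ks <- vapply(fit, function(f) {
      ks_distance(minima, function(x) dist_cdf(f$dist, x))
    }, numeric(1))
  }
  list(domain_predicted = dom$domain, fitted_limit = fit,
       ks_distance = ks, n_causes = n_causes, n_reps = n_reps)
}

#' One-sample Kolmogorov-Smirnov distance
#'
#' Supremum distance between the empirical cdf of `x` and a reference cdf.
#'
#' @param x Numeric sample.
#' @param cdf Vectorised cdf function.
#' @return The KS statistic.
#' @export
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx))
}
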