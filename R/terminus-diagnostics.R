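# Lower-terminus shape diagnostics: which minimum domain of attraction does an
# initial time-to-event law belong to? Flat behaviour at the terminus (all cdf
# derivatives vanish) leads to a Gompertz limit for minima; regular variation
# with index rho leads to a Weibull limit with shape rho.

# log F(terminus + t), accurate far into the lower tail (closed forms where
# the plain cdf would underflow)
log_cdf_offset <- function(d, t) {
  p <- d$params
  log_from_H <- function(H) ifelse(H > 1e-8, log(-expm1(-H)), log(H) + log1p(-H / 2))
  switch(d$family,
    gompertz = log_from_H(if (p$theta == 0) p$lam * t else
      p$lam / p$theta * expm1(p$theta * t)),
    makeham = log_from_H(p$c * t +
      (if (p$theta == 0) p$lam * t else p$lam / p$theta * expm1(p$theta * t))),
    weibull = log_from_H(p$alpha * t^p$gamma),
    flat = -p$b / t,
    regvar = pmin(0, log(p$c) + p$rho * log(t)),
    log(dist_cdf(d, dist_terminus(d) + t))
  )
}

#' One-sided cdf derivatives at the lower terminus
#'
#' Estimates `F'(a+), F''(a+), ...` up to order `k` by forward finite
#' differences with Richardson step-halving refinement. A law that is flat at
#' its terminus has all of these equal to zero.
#'
#' @param d An `ebmc_dist` with a finite lower terminus.
#' @param k Highest derivative order (`<= 4`; numerical stability bound).
#' @param eps Base step in years (`> 0`).
#' @return A tibble with columns `order`, `estimate` (Richardson-refined) and
#'   `error` (the step-halving discrepancy, an error estimate).
#' @examples
#' derivatives_at_terminus(dist_flat(b = 1))          # all ~ 0
#' derivatives_at_terminus(dist_regvar(1, 1, 0))      # first ~ 1
#' @export
derivatives_at_terminus <- function(d, k = 4, eps = 1e-3) {
  stopifnot(inherits(d, "ebmc_dist"), k >= 1, k <= 4, eps > 0)
  a <- dist_terminus(d)
  fwd <- function(j, h) {
    i <- 0:j
    sum((-1)^(j - i) * choose(j, i) * dist_cdf(d, a + i * h)) / h^j
  }
  rows <- lapply(seq_len(k), function(j) {
    d1 <- fwd(j, eps)
    d2 <- fwd(j, eps / 2)
    tibble::tibble(order = j,
                   estimate = 2 * d2 - d1,  # first-order Richardson
                   error = abs(d2 - d1))
  })
  dplyr::bind_rows(rows)
}

#' Karamata regular-variation index at the lower terminus
#'
#' Estimates the regular-variation index `rho` of the cdf at its lower
#' terminus from the slope of `log F(a + t)` against `log t` as `t -> 0`,
#' i.e. the exponent in the Karamata limit of `F(x t) / F(t)`. A flat law
#' (all derivatives zero) has slope growing without bound and is flagged
#' `divergent`.
#'
#' @param d An `ebmc_dist` with a finite lower terminus.
#' @param t_grid Decreasing positive offsets from the terminus.
#' @param x_probe Ratio points `x > 0` used for the diagnostic check that
#'   `F(x t) / F(t) ~ x^rho` at the smallest grid offset.
#' @return A list with `rho` (estimate, `NA` when divergent), `se` (spread of
#'   the local slopes used), `divergent` (logical) and `diagnostics` (tibble
#'   of local slopes; probe ratio errors as an attribute).
#' @examples
#' karamata_index(dist_weibull(1, 2))$rho        # ~ 2
#' karamata_index(dist_flat(1))$divergent        # TRUE
#' @export
karamata_index <- function(d, t_grid = 10^seq(-1, -7, by = -0.5),
                           x_probe = c(0.5, 2)) {
  stopifnot(inherits(d, "ebmc_dist"), all(t_grid > 0), all(x_probe > 0))
  t_grid <- sort(t_grid, decreasing = TRUE)
  lf <- log_cdf_offset(d, t_grid)
  usable <- is.finite(lf)
  if (!any(usable)) stop("cdf is identically 0 on the offset grid", call. = FALSE)
  # local slopes on the log-log scale, ordered from largest to smallest t
  lt <- log(t_grid)
  slopes <- diff(lf[usable]) / diff(lt[usable])
  diag_tbl <- tibble::tibble(
    t_upper = t_grid[usable][-1],
    slope = slopes
  )
  # flat laws: slope ~ b/t explodes as t -> 0 (or log F underflows entirely)
  increasing <- length(slopes) >= 2 &&
    all(diff(slopes) > -1e-8) && slopes[length(slopes)] > slopes[1]
  underflow <- sum(usable) < length(t_grid)
  divergent <- (max(slopes) > 50 && increasing) ||
    (underflow && max(slopes) > 50)
  tail_n <- min(3L, length(slopes))
  tail_slopes <- utils::tail(slopes, tail_n)
  rho <- if (divergent) NA_real_ else mean(tail_slopes)
  se <- if (divergent) NA_real_ else stats::sd(tail_slopes) / sqrt(tail_n)
  if (!divergent) {
    t0 <- min(t_grid[usable])
    probe_err <- vapply(x_probe, function(xp) {
      r <- log_cdf_offset(d, xp * t0) - log_cdf_offset(d, t0)
      abs(r - rho * log(xp))
    }, numeric(1))
    attr(diag_tbl, "probe_log_ratio_error") <- probe_err
  }
  list(rho = rho, se = se, divergent = divergent, diagnostics = diag_tbl)
}

#' Classify the minimum domain of attraction of an initial law
#'
#' Combines [derivatives_at_terminus()] and [karamata_index()]:
#' `gompertz_domain` when all terminus derivatives are numerically zero
#' (`< flat_tol`) *and* the Karamata slope diverges; `weibull_domain` (with
#' the estimated index `rho`) when the slope converges to a finite stable
#' value; `undetermined` otherwise — the classifier never guesses.
#'
#' Note that the Gompertz *law itself*, used as an initial distribution, is
#' not flat at its terminus (`F(x) ~ lam * (x - a)`), so it classifies
#' `weibull_domain` with `rho ~ 1`: being an attracting limit and being in a
#' domain of attraction are different properties.
#'
#' @inheritParams karamata_index
#' @param flat_tol Numerical flatness threshold on the derivative estimates.
#' @return A list with `domain` (one of `"gompertz_domain"`,
#'   `"weibull_domain"`, `"undetermined"`), `rho` (`NA` unless Weibull) and
#'   the two underlying diagnostic objects.
#' @examples
#' classify_domain(dist_flat(2, terminus = 10))$domain     # gompertz_domain
#' classify_domain(dist_weibull(0.5, 3))$rho               # ~ 3
#' @export
classify_domain <- function(d, flat_tol = 1e-6) {
  stopifnot(inherits(d, "ebmc_dist"))
  if (!is.finite(dist_terminus(d))) stop("distribution needs a finite lower terminus")
  der <- derivatives_at_terminus(d)
  kar <- karamata_index(d)
  flat <- all(abs(der$estimate) < flat_tol) & all(der$error < flat_tol)
  stable <- !kar$divergent && is.finite(kar$rho) &&
    (is.na(kar$se) || kar$se < 0.05 * max(kar$rho, 1))
  domain <- if (flat && kar$divergent) {
    "gompertz_domain"
  } else if (!flat && stable) {
    "weibull_domain"
  } else {
    "undetermined"
  }
  list(domain = domain,
       rho = if (domain == "weibull_domain") kar$rho else NA_real_,
       derivatives = der, karamata = kar)
}
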