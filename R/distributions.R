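#' Parametric time-to-event families
#'
#' Constructors for the time-to-event laws used throughout the package. Every
#' distribution carries an explicit lower terminus `a` (an age in years below
#' which the event cannot occur), so that the earliest-reproduction-age
#' restriction of the causal model is a single convention: for all families,
#' `F(x) = 0`, `S(x) = 1`, `f(x) = 0` and `h(x) = 0` for `x <= a`.
#'
#' Families:
#' * `dist_gompertz(lam, theta, terminus)`: hazard
#'   `h(x) = lam * exp(theta * (x - a))`; `lam > 0` is the initial hazard at
#'   the terminus and `theta >= 0` the exponential rate of aging.
#'   `theta = 0` gives the exponential law with rate `lam`.
#' * `dist_weibull(alpha, gamma, terminus)`: hazard
#'   `h(x) = alpha * gamma * (x - a)^(gamma - 1)`, survival
#'   `S(x) = exp(-alpha * (x - a)^gamma)`. `gamma = 1` gives the exponential
#'   law with rate `alpha`.
#' * `dist_makeham(lam, theta, c, terminus)`: Gompertz plus an age-independent
#'   additive hazard `c` (extrinsic mortality).
#' * `dist_flat(b, terminus)`: the canonical smooth cdf that is *flat* at its
#'   lower terminus, `F(x) = exp(-b / (x - a))` for `x > a`; every derivative
#'   of `F` vanishes at `a+`. Members of this family lie in the minimum
#'   domain of attraction of the Gompertz distribution.
#' * `dist_regvar(c, rho, terminus, cap_age)`: cdf regularly varying at the
#'   terminus with index `rho`, `F(x) = min(1, c * (x - a)^rho)`; clipped to 1
#'   at `cap_age` (defaults to the age where `c * (x - a)^rho` reaches 1).
#'   Members lie in the minimum domain of attraction of the Weibull
#'   distribution with shape `rho`. `dist_regvar(1, 1, 0)` is uniform(0, 1).
#' * `dist_lognormal(meanlog, sdlog, terminus)` and
#'   `dist_gamma(shape, rate, terminus)`: shifted unimodal laws used for
#'   genetic component causes.
#' * `dist_fixed(value)`: a degenerate point mass, convenient for tests and
#'   threshold-exposure ingredients.
#' * [dist_threshold()]: cumulative-exposure threshold crossing (its own page).
#'
#' @param lam Initial hazard rate per year (`> 0`).
#' @param theta Exponential rate-of-aging parameter per year (`>= 0`).
#' @param alpha Scale-rate parameter (`> 0`, units year^-gamma).
#' @param gamma Shape parameter (`> 0`).
#' @param c For `dist_makeham`, the additive age-independent hazard (`>= 0`);
#'   for `dist_regvar`, the leading coefficient (`> 0`).
#' @param b Steepness parameter of the flat family in years (`> 0`).
#' @param rho Regular-variation index (`> 0`).
#' @param cap_age Age at which the regularly-varying cdf is clipped to 1.
#' @param meanlog,sdlog Log-scale location and scale of the shifted lognormal.
#' @param shape,rate Shape and rate of the shifted gamma.
#' @param value Location of the degenerate point mass.
#' @param terminus Lower endpoint age in years (`>= 0`).
#'
#' @return An object of class `ebmc_dist`.
#' @examples
#' g <- dist_gompertz(lam = 0.01, theta = 0.1, terminus = 10)
#' dist_hazard(g, c(10, 20))      # 0.01, 0.01 * exp(1)
#' dist_quantile(g, 0.5)
#' @name distributions
NULL

new_dist <- function(family, params, classes = character()) {
  structure(list(family = family, params = params),
            class = c(classes, paste0("ebmc_dist_", family), "ebmc_dist"))
}

check_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("`%s` must be a single finite %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(x)
}

#' @rdname distributions
#' @export
dist_gompertz <- function(lam, theta, terminus = 0) {
  check_pos(lam, "lam"); check_pos(theta, "theta", strict = FALSE)
  check_pos(terminus, "terminus", strict = FALSE)
  new_dist("gompertz", list(lam = lam, theta = theta, terminus = terminus))
}

#' @rdname distributions
#' @export
dist_weibull <- function(alpha, gamma, terminus = 0) {
  check_pos(alpha, "alpha"); check_pos(gamma, "gamma")
  check_pos(terminus, "terminus", strict = FALSE)
  new_dist("weibull", list(alpha = alpha, gamma = gamma, terminus = terminus))
}

#' @rdname distributions
#' @export
dist_makeham <- function(lam, theta, c, terminus = 0) {
  check_pos(lam, "lam"); check_pos(theta, "theta", strict = FALSE)
  check_pos(c, "c", strict = FALSE); check_pos(terminus, "terminus", strict = FALSE)
  new_dist("makeham", list(lam = lam, theta = theta, c = c, terminus = terminus))
}

#' @rdname distributions
#' @export
dist_flat <- function(b, terminus = 0) {
  check_pos(b, "b"); check_pos(terminus, "terminus", strict = FALSE)
  new_dist("flat", list(b = b, terminus = terminus))
}

#' @rdname distributions
#' @export
dist_regvar <- function(c, rho, terminus = 0, cap_age = NULL) {
  check_pos(c, "c"); check_pos(rho, "rho")
  check_pos(terminus, "terminus", strict = FALSE)
  natural_cap <- terminus + (1 / c)^(1 / rho)
  if (is.null(cap_age)) cap_age <- natural_cap
  if (cap_age < terminus) stop("`cap_age` must be >= terminus", call. = FALSE)
  new_dist("regvar", list(c = c, rho = rho, terminus = terminus,
                          cap_age = cap_age))
}

#' @rdname distributions
#' @export
dist_lognormal <- function(meanlog, sdlog, terminus = 0) {
  check_pos(sdlog, "sdlog"); check_pos(terminus, "terminus", strict = FALSE)
  stopifnot(is.finite(meanlog))
  new_dist("lognormal_shifted",
           list(meanlog = meanlog, sdlog = sdlog, terminus = terminus))
}

#' @rdname distributions
#' @export
dist_gamma <- function(shape, rate, terminus = 0) {
  check_pos(shape, "shape"); check_pos(rate, "rate")
  check_pos(terminus, "terminus", strict = FALSE)
  new_dist("gamma_shifted", list(shape = shape, rate = rate, terminus = terminus))
}

#' @rdname distributions
#' @export
dist_fixed <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  new_dist("fixed", list(value = value, terminus = value))
}

#' Threshold-exposure time-to-event law
#'
#' Models an environmental component cause whose causal role expresses when a
#' cumulative exposure reaches a (possibly random) threshold. Exposure starts
#' at a random onset age and accrues linearly at a random positive rate, so
#' the event age is `onset + threshold / rate`, the three ingredients drawn
#' independently. The cdf and pdf are evaluated by averaging the threshold
#' law over a deterministic quantile grid of the onset and rate laws
#' (midpoint rule, `n_grid` nodes per ingredient); degenerate ingredients are
#' exact.
#'
#' @param onset `ebmc_dist`: age at which exposure begins.
#' @param rate `ebmc_dist`: accrual rate per year; must have positive support.
#' @param threshold `ebmc_dist`: positive cumulative-exposure threshold.
#' @param n_grid Quadrature nodes per random ingredient (default 64).
#' @return An object of class `ebmc_dist`.
#' @seealso [sample_threshold_crossing()]
#' @examples
#' d <- dist_threshold(dist_fixed(0), dist_fixed(1), dist_fixed(5))
#' dist_sample(d, 3, seed = 1)  # all 5
#' @export
dist_threshold <- function(onset, rate, threshold, n_grid = 64) {
  stopifnot(inherits(onset, "ebmc_dist"), inherits(rate, "ebmc_dist"),
            inherits(threshold, "ebmc_dist"))
  if (dist_quantile(rate, 0.999) <= 0) {
    stop("`rate` must have positive support", call. = FALSE)
  }
  terminus <- dist_quantile(onset, 0)
  new_dist("threshold", list(onset = onset, rate = rate, threshold = threshold,
                             n_grid = n_grid, terminus = terminus))
}

#' @export
print.ebmc_dist <- function(x, ...) {
  pp <- x$params[!vapply(x$params, inherits, logical(1), "ebmc_dist")]
  pp <- pp[vapply(pp, is.numeric, logical(1))]
  cat(sprintf("<ebmc_dist: %s> %s\n", x$family,
              paste(names(pp), signif(unlist(pp), 4), sep = "=", collapse = ", ")))
  invisible(x)
}

dist_terminus <- function(d) d$params$terminus

# cumulative hazard, vectorised; defined for x relative to absolute age
cumhaz <- function(d, x) {
  a <- dist_terminus(d); t <- pmax(x - a, 0)
  p <- d$params
  switch(d$family,
    gompertz = if (p$theta == 0) p$lam * t else p$lam / p$theta * expm1(p$theta * t),
    weibull  = p$alpha * t^p$gamma,
    makeham  = p$c * t +
      (if (p$theta == 0) p$lam * t else p$lam / p$theta * expm1(p$theta * t)),
    -log(dist_survival(d, x))
  )
}

#' Evaluate a distribution channel
#'
#' `dist_cdf()`, `dist_pdf()`, `dist_survival()` and `dist_hazard()` evaluate
#' the four channels of a time-to-event law; `dist_eval()` dispatches on a
#' channel name. Below the lower terminus the conventions are `F = 0`,
#' `S = 1`, `f = 0`, `h = 0`; where `S = 0` the hazard is `+Inf` by
#' convention.
#'
#' @param d An `ebmc_dist`.
#' @param x Vector of ages (years), finite.
#' @param channel One of `"cdf"`, `"pdf"`, `"survival"`, `"hazard"`.
#' @return Numeric vector, same length as `x`.
#' @export
dist_eval <- function(d, x, channel = c("cdf", "pdf", "survival", "hazard")) {
  channel <- match.arg(channel)
  switch(channel,
    cdf = dist_cdf(d, x), pdf = dist_pdf(d, x),
    survival = dist_survival(d, x), hazard = dist_hazard(d, x))
}

#' @rdname dist_eval
#' @export
dist_cdf <- function(d, ...) UseMethod("dist_cdf")

#' @rdname dist_eval
#' @export
dist_cdf.ebmc_dist <- function(d, x) {
  stopifnot(inherits(d, "ebmc_dist"), all(is.finite(x)))
  a <- dist_terminus(d); p <- d$params
  out <- switch(d$family,
    gompertz = ,
    weibull = ,
    makeham = -expm1(-cumhaz(d, x)),
    flat = ifelse(x > a, exp(-p$b / pmax(x - a, .Machine$double.xmin)), 0),
    regvar = pmin(1, ifelse(x >= p$cap_age, 1, p$c * pmax(x - a, 0)^p$rho)),
    lognormal_shifted = stats::plnorm(pmax(x - a, 0), p$meanlog, p$sdlog),
    gamma_shifted = stats::pgamma(pmax(x - a, 0), p$shape, p$rate),
    fixed = as.numeric(x >= p$value),
    threshold = threshold_channel(d, x, "cdf"),
    stop("unknown family ", d$family)
  )
  pmin(pmax(out, 0), 1)
}

#' @rdname dist_eval
#' @export
dist_survival <- function(d, ...) UseMethod("dist_survival")

#' @rdname dist_eval
#' @export
dist_survival.ebmc_dist <- function(d, x) {
  stopifnot(inherits(d, "ebmc_dist"), all(is.finite(x)))
  switch(d$family,
    gompertz = ,
    weibull = ,
    makeham = exp(-cumhaz(d, x)),
    1 - dist_cdf(d, x)
  )
}

#' @rdname dist_eval
#' @export
dist_pdf <- function(d, ...) UseMethod("dist_pdf")

#' @rdname dist_eval
#' @export
dist_pdf.ebmc_dist <- function(d, x) {
  stopifnot(inherits(d, "ebmc_dist"), all(is.finite(x)))
  a <- dist_terminus(d); p <- d$params; t <- x - a
  out <- switch(d$family,
    gompertz = ifelse(t >= 0, p$lam * exp(p$theta * t) * dist_survival(d, x), 0),
    weibull = ifelse(t > 0, p$alpha * p$gamma * t^(p$gamma - 1) *
                       dist_survival(d, x), 0),
    makeham = ifelse(t >= 0, (p$c + p$lam * exp(p$theta * t)) *
                       dist_survival(d, x), 0),
    flat = ifelse(t > 0, exp(-p$b / pmax(t, .Machine$double.xmin)) *
                    p$b / pmax(t, .Machine$double.xmin)^2, 0),
    regvar = ifelse(t > 0 & x < p$cap_age & p$c * t^p$rho < 1,
                    p$c * p$rho * t^(p$rho - 1), 0),
    lognormal_shifted = ifelse(t > 0, stats::dlnorm(pmax(t, 0), p$meanlog, p$sdlog), 0),
    gamma_shifted = ifelse(t > 0, stats::dgamma(pmax(t, 0), p$shape, p$rate), 0),
    fixed = stop("degenerate law has no density", call. = FALSE),
    threshold = threshold_channel(d, x, "pdf"),
    stop("unknown family ", d$family)
  )
  pmax(out, 0)
}

#' @rdname dist_eval
#' @export
dist_hazard <- function(d, ...) UseMethod("dist_hazard")

#' @rdname dist_eval
#' @export
dist_hazard.ebmc_dist <- function(d, x) {
  stopifnot(inherits(d, "ebmc_dist"), all(is.finite(x)))
  a <- dist_terminus(d); p <- d$params; t <- x - a
  out <- switch(d$family,
    gompertz = ifelse(t >= 0, p$lam * exp(p$theta * t), 0),
    weibull = ifelse(t > 0, p$alpha * p$gamma * t^(p$gamma - 1),
                     ifelse(t == 0 & p$gamma == 1, p$alpha, 0)),
    makeham = ifelse(t >= 0, p$c + p$lam * exp(p$theta * t), 0),
    {
      S <- dist_survival(d, x)
      f <- dist_pdf(d, x)
      ifelse(t <= 0, 0, ifelse(S > 0, f / S, Inf))
    }
  )
  out
}

#' Quantile function
#'
#' Inverts the cdf: `dist_cdf(d, dist_quantile(d, q)) == q` to within `1e-10`.
#' Closed forms are used where available; otherwise a bracketed root search.
#' `q = 0` returns the lower terminus.
#'
#' @inheritParams dist_eval
#' @param q Vector of probabilities in `[0, 1)`.
#' @return Vector of ages.
#' @export
dist_quantile <- function(d, ...) UseMethod("dist_quantile")

#' @rdname dist_quantile
#' @export
dist_quantile.ebmc_dist <- function(d, q) {
  stopifnot(inherits(d, "ebmc_dist"))
  if (any(q < 0 | q >= 1 | !is.finite(q))) {
    stop("`q` must lie in [0, 1)", call. = FALSE)
  }
  a <- dist_terminus(d); p <- d$params
  switch(d$family,
    gompertz = {
      H <- -log1p(-q)  # = -log(1 - q)
      if (p$theta == 0) a + H / p$lam
      else a + log1p(p$theta * H / p$lam) / p$theta
    },
    weibull = a + (-log1p(-q) / p$alpha)^(1 / p$gamma),
    makeham = quantile_root(d, q),
    flat = ifelse(q == 0, a, a + p$b / (-log(q))),
    regvar = a + (q / p$c)^(1 / p$rho),
    lognormal_shifted = a + stats::qlnorm(q, p$meanlog, p$sdlog),
    gamma_shifted = a + stats::qgamma(q, p$shape, p$rate),
    fixed = rep(p$value, length(q)),
    threshold = quantile_root(d, q),
    stop("unknown family ", d$family)
  )
}

# bracketed root search fallback for families without a closed-form inverse
quantile_root <- function(d, q) {
  a <- dist_terminus(d)
  vapply(q, function(qi) {
    if (qi == 0) return(a)
    hi <- a + 1
    while (dist_cdf(d, hi) < qi && hi < a + 1e7) hi <- a + (hi - a) * 2
    stats::uniroot(function(x) dist_cdf(d, x) - qi, lower = a, upper = hi,
                   tol = 1e-12)$root
  }, numeric(1))
}

#' Draw seeded samples
#'
#' Inverse-transform sampling (so draws respect [dist_quantile()]); the
#' threshold-exposure family composes its three ingredients instead. With a
#' `seed`, the draw is reproducible and the caller's RNG state is untouched.
#'
#' @inheritParams dist_eval
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of ages, length `n`.
#' @export
dist_sample <- function(d, n, seed = NULL) {
  stopifnot(inherits(d, "ebmc_dist"), n >= 1)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, dist_sample(d, n, seed = NULL)))
  }
  if (d$family == "threshold") {
    p <- d$params
    onset <- dist_draw(p$onset, n)
    rate <- positive_draws(p$rate, n)
    thr <- dist_draw(p$threshold, n)
    return(onset + thr / rate)
  }
  dist_draw(d, n)
}

# draw using the current RNG stream (no seed handling)
dist_draw <- function(d, n) {
  if (d$family == "mixture") return(sample_mixture(d, n)$age)
  if (d$family == "fixed") return(rep(d$params$value, n))
  if (d$family == "threshold") return(dist_sample(d, n, seed = NULL))
  dist_quantile(d, stats::runif(n))
}

# redraw non-positive rates; the rejection count is reported via a message
positive_draws <- function(d, n) {
  x <- dist_draw(d, n)
  rejected <- 0L
  for (i in seq_len(50)) {
    bad <- which(x <= 0)
    if (!length(bad)) break
    rejected <- rejected + length(bad)
    x[bad] <- dist_draw(d, length(bad))
  }
  if (rejected > 0) message(rejected, " non-positive rate draw(s) rejected and redrawn")
  if (any(x <= 0)) stop("rate law keeps producing non-positive draws", call. = FALSE)
  x
}

#' Sample threshold-crossing ages
#'
#' Convenience wrapper: each draw is `onset + threshold / rate`, the three
#' ingredients drawn independently (non-positive rate draws are rejected and
#' redrawn, with a message).
#'
#' @param params An `ebmc_dist` of family `threshold` (see [dist_threshold()]).
#' @inheritParams dist_sample
#' @return Numeric vector of event ages.
#' @export
sample_threshold_crossing <- function(params, n, seed = NULL) {
  stopifnot(params$family == "threshold")
  dist_sample(params, n, seed = seed)
}

# quadrature evaluation of the threshold-crossing cdf/pdf:
# F(x) = E_{onset, rate}[ F_thr((x - onset) * rate) ]
threshold_channel <- function(d, x, what = c("cdf", "pdf")) {
  what <- match.arg(what)
  p <- d$params
  m <- p$n_grid
  nodes <- function(dd) {
    if (dd$family == "fixed") return(dd$params$value)
    dist_quantile(dd, (seq_len(m) - 0.5) / m)
  }
  o <- nodes(p$onset)
  r <- nodes(p$rate)
  r <- r[r > 0]
  if (!length(r)) stop("rate law has no positive quantiles", call. = FALSE)
  grid <- expand.grid(o = o, r = r)
  vapply(x, function(xi) {
    t_eff <- (xi - grid$o) * grid$r
    ok <- t_eff > 0
    if (!any(ok)) return(0)
    if (what == "cdf") {
      mean(ifelse(ok, dist_cdf(p$threshold, pmax(t_eff, 0)), 0))
    } else {
      if (p$threshold$family == "fixed") {
        stop("pdf of threshold law with degenerate threshold is not defined",
             call. = FALSE)
      }
      mean(ifelse(ok, grid$r * dist_pdf(p$threshold, pmax(t_eff, 0)), 0))
    }
  }, numeric(1))
}

#' Check density unimodality on a grid
#'
#' Evaluates the density on a 512-point grid spanning the central 99.9%
#' quantile range and counts strict local maxima after collapsing ties
#' (tolerance `1e-12`). Used to validate late-onset genetic timing laws.
#'
#' @inheritParams dist_eval
#' @return `TRUE` if exactly one strict local maximum is found.
#' @export
is_unimodal <- function(d) {
  lo <- dist_quantile(d, 5e-4)
  hi <- dist_quantile(d, 1 - 5e-4)
  xs <- seq(lo, hi, length.out = 512)
  f <- dist_pdf(d, xs)
  keep <- c(TRUE, abs(diff(f)) > 1e-12)  # collapse tied runs
  f <- f[keep]
  if (length(f) < 3) return(TRUE)
  sign_changes <- diff(sign(diff(f)))
  sum(sign_changes < 0) <= 1
}
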