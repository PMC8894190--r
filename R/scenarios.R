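# Healthy-aging scenario projector: morbidity/mortality curve pairs under
# health-promotion, postponed-aging and combined interventions, with
# life-expectancy, unhealthy-years and rectangularization summaries.

#' Intervention specifications
#'
#' * `intervention_none()`: identity.
#' * `intervention_health_promotion(eref_reduction)`: primary prevention —
#'   reduces the contribution of sufficient causes containing evolutionarily
#'   recent environmental factors by multiplying each curve's Weibull weight
#'   `(1 - p)` by `(1 - eref_reduction)`. `eref_reduction` may be a single
#'   fraction or a length-2 vector `c(morbidity, mortality)`;
#'   `eref_reduction = 1` yields the pure-Gompertz "rectangularized" curve
#'   (complete elimination of recent environmental exposures).
#' * `intervention_postponed_aging(theta_scale, shift_years)`: modification of
#'   the fundamental aging process — rescales the Gompertz rate of aging
#'   `theta` by `theta_scale` and/or delays the whole intrinsic schedule by
#'   `shift_years` (both mixture components' termini shift, a pure
#'   translation), applied to BOTH curves equally.
#' * `intervention_combined(health_promotion, postponed_aging)`: composes the
#'   two.
#'
#' @param eref_reduction Fraction(s) in `[0, 1]`.
#' @param theta_scale Multiplier in `(0, 1]` on the rate of aging.
#' @param shift_years Delay in years (`>= 0`).
#' @param health_promotion,postponed_aging Component interventions.
#' @return An `ebmc_intervention` object.
#' @name interventions
NULL

#' @rdname interventions
#' @export
intervention_none <- function() {
  structure(list(type = "none"), class = "ebmc_intervention")
}

#' @rdname interventions
#' @export
intervention_health_promotion <- function(eref_reduction) {
  stopifnot(is.numeric(eref_reduction), length(eref_reduction) %in% 1:2,
            all(eref_reduction >= 0), all(eref_reduction <= 1))
  if (length(eref_reduction) == 1L) {
    eref_reduction <- c(morbidity = eref_reduction, mortality = eref_reduction)
  } else {
    names(eref_reduction) <- c("morbidity", "mortality")
  }
  structure(list(type = "health_promotion", eref_reduction = eref_reduction),
            class = "ebmc_intervention")
}

#' @rdname interventions
#' @export
intervention_postponed_aging <- function(theta_scale = 1, shift_years = 0) {
  stopifnot(theta_scale > 0, theta_scale <= 1, shift_years >= 0)
  structure(list(type = "postponed_aging", theta_scale = theta_scale,
                 shift_years = shift_years), class = "ebmc_intervention")
}

#' @rdname interventions
#' @export
intervention_combined <- function(health_promotion, postponed_aging) {
  stopifnot(inherits(health_promotion, "ebmc_intervention"),
            health_promotion$type == "health_promotion",
            inherits(postponed_aging, "ebmc_intervention"),
            postponed_aging$type == "postponed_aging")
  structure(list(type = "combined", health_promotion = health_promotion,
                 postponed_aging = postponed_aging),
            class = "ebmc_intervention")
}

# apply an intervention to one curve's mixture; `curve` is "morbidity" or
# "mortality" (health promotion may differ per curve)
transform_mixture <- function(mp, intervention, curve) {
  switch(intervention$type,
    none = mp,
    health_promotion = {
      r <- intervention$eref_reduction[[curve]]
      w <- (1 - mp$params$p) * (1 - r)
      mixture_params(1 - w, mp$params$gompertz, mp$params$weibull)
    },
    postponed_aging = {
      g <- mp$params$gompertz$params
      w <- mp$params$weibull$params
      mixture_params(mp$params$p,
        dist_gompertz(g$lam, g$theta * intervention$theta_scale,
                      g$terminus + intervention$shift_years),
        dist_weibull(w$alpha, w$gamma, w$terminus + intervention$shift_years))
    },
    combined = {
      transform_mixture(
        transform_mixture(mp, intervention$health_promotion, curve),
        intervention$postponed_aging, curve)
    },
    stop("unknown intervention type", call. = FALSE)
  )
}

#' Specify a healthy-aging scenario
#'
#' A scenario couples a baseline morbidity mixture (first onset of
#' aging-related disease) and mortality mixture (intrinsic death) with an
#' intervention, evaluated on a common age grid.
#'
#' @param morbidity,mortality [mixture_params()] objects; morbidity survival
#'   should lie below mortality survival pointwise (validated at evaluation,
#'   not enforced).
#' @param intervention An intervention from [interventions].
#' @param horizon Upper age of the grid (years, default 110).
#' @param step Grid step (years, default 0.1).
#' @return An `ebmc_scenario` object.
#' @seealso [apply_scenario()], [default_scenario()]
#' @export
scenario_spec <- function(morbidity, mortality,
                          intervention = intervention_none(),
                          horizon = 110, step = 0.1) {
  stopifnot(inherits(morbidity, "mixture_params"),
            inherits(mortality, "mixture_params"),
            inherits(intervention, "ebmc_intervention"),
            is.finite(horizon), horizon > 0, step > 0)
  terminus <- min(dist_terminus(morbidity), dist_terminus(mortality))
  stopifnot(horizon > terminus)
  structure(list(morbidity = morbidity, mortality = mortality,
                 intervention = intervention, terminus = terminus,
                 horizon = horizon, step = step),
            class = "ebmc_scenario")
}

#' Shipped default scenario configuration
#'
#' Baseline mixtures with terminus 10 y and horizon 110 y, calibrated so the
#' baseline mortality life expectancy is about 80 years: mortality is 80%
#' Gompertz (`lam = 4e-5`, `theta = 0.1`) and 20% Weibull (`alpha =
#' 7.2e-10`, `gamma = 5`); morbidity uses the same weights with the Gompertz
#' component about 6 years earlier and the Weibull component about 12 years
#' earlier (disease driven by recent environmental exposures carries the
#' longer morbid period). Intended for the qualitative ordering analyses;
#' the curve shapes are illustrative, not fitted to any population.
#'
#' @param intervention Intervention to attach (default none).
#' @return An `ebmc_scenario`.
#' @export
default_scenario <- function(intervention = intervention_none()) {
  mortality <- mixture_params(0.8,
    dist_gompertz(lam = 4e-5, theta = 0.1, terminus = 10),
    dist_weibull(alpha = 7.2e-10, gamma = 5, terminus = 10))
  morbidity <- mixture_params(0.8,
    dist_gompertz(lam = 4e-5 * exp(0.1 * 6), theta = 0.1, terminus = 10),
    dist_weibull(alpha = 54.4^-5, gamma = 5, terminus = 10))
  scenario_spec(morbidity, mortality, intervention)
}

#' Evaluate a scenario into a curve set
#'
#' Evaluates the baseline (pre) and post-intervention morbidity and mortality
#' survival curves on the age grid and computes the summaries: life
#' expectancy (LE), healthy life expectancy (HLE), unhealthy years
#' (`LE - HLE`, the area between the mortality and morbidity curves) and
#' rectangularity, for pre and post. If the morbidity curve rises above the
#' mortality curve anywhere (disease after death), the output is flagged and
#' the summaries carry `valid = FALSE`.
#'
#' @param spec An [scenario_spec()].
#' @return An `ebmc_curve_set`: `curves` (tibble `age`,
#'   `S_morbidity_pre`, `S_morbidity_post`, `S_mortality_pre`,
#'   `S_mortality_post`), `summaries` (tibble), `valid`, `spec`.
#' @export
apply_scenario <- function(spec) {
  stopifnot(inherits(spec, "ebmc_scenario"))
  ages <- seq(spec$terminus, spec$horizon, by = spec$step)
  morb_post <- transform_mixture(spec$morbidity, spec$intervention, "morbidity")
  mort_post <- transform_mixture(spec$mortality, spec$intervention, "mortality")
  curves <- tibble::tibble(
    age = ages,
    S_morbidity_pre = dist_survival(spec$morbidity, ages),
    S_morbidity_post = dist_survival(morb_post, ages),
    S_mortality_pre = dist_survival(spec$mortality, ages),
    S_mortality_post = dist_survival(mort_post, ages)
  )
  ord_ok <- function(sm, st) all(sm <= st + 1e-9)
  valid <- ord_ok(curves$S_morbidity_pre, curves$S_mortality_pre) &&
    ord_ok(curves$S_morbidity_post, curves$S_mortality_post)
  if (!valid) {
    warning("morbidity survival exceeds mortality survival somewhere; summaries flagged invalid",
            call. = FALSE)
  }
  summarise_when <- function(when) {
    sm <- curves[[paste0("S_morbidity_", when)]]
    st <- curves[[paste0("S_mortality_", when)]]
    le <- life_expectancy(ages, st)
    hle <- life_expectancy(ages, sm)
    rect <- rectangularity(ages, st)
    tibble::tibble(when = when, LE = le, HLE = hle,
                   unhealthy_years = le - hle,
                   rect_iqr = rect$iqr_years,
                   rect_slope_at_median = rect$slope_at_median,
                   valid = valid)
  }
  summaries <- dplyr::bind_rows(summarise_when("pre"), summarise_when("post"))
  structure(list(curves = curves, summaries = summaries, valid = valid,
                 morbidity_post = morb_post, mortality_post = mort_post,
                 spec = spec),
            class = "ebmc_curve_set")
}

#' @export
print.ebmc_curve_set <- function(x, ...) {
  cat(sprintf("<ebmc_curve_set> intervention: %s%s\n", x$spec$intervention$type,
              if (!x$valid) " [INVALID ordering]" else ""))
  print(x$summaries)
  invisible(x)
}

#' Long-format curves of a scenario evaluation
#'
#' @param x An `ebmc_curve_set`.
#' @param ... Unused.
#' @return Tibble `age`, `curve` (morbidity/mortality), `when` (pre/post),
#'   `survival`.
#' @method tidy ebmc_curve_set
#' @export
tidy.ebmc_curve_set <- function(x, ...) {
  x$curves |>
    tidyr::pivot_longer(-"age", names_to = "key", values_to = "survival") |>
    tidyr::separate_wider_regex("key",
      c("S_", curve = "[a-z]+", "_", when = "pre|post")) |>
    dplyr::select("age", "curve", "when", "survival")
}

#' Life expectancy from a survival curve on a grid
#'
#' `terminus + integral of S` by the trapezoidal rule. The quadrature error
#' is estimated by step halving (comparing against the every-other-point
#' grid); a warning is issued if the bound exceeds 0.05 years.
#'
#' @param ages Increasing age grid starting at the curve's terminus.
#' @param survival Survival values on the grid (in `[0, 1]`, nonincreasing).
#' @return Life expectancy in years, with the error bound as attribute
#'   `quadrature_error`.
#' @export
life_expectancy <- function(ages, survival) {
  stopifnot(length(ages) == length(survival), length(ages) >= 3,
            all(diff(ages) > 0), all(survival >= -1e-12), all(survival <= 1 + 1e-12))
  full <- pracma::trapz(ages, survival)
  idx <- seq(1, length(ages), by = 2)
  if (idx[length(idx)] != length(ages)) idx <- c(idx, length(ages))
  coarse <- pracma::trapz(ages[idx], survival[idx])
  err <- abs(full - coarse) / 3  # Richardson error estimate for trapezoids
  if (err > 0.05) warning("age grid too coarse: life-expectancy quadrature error bound ",
                          signif(err, 2), " y", call. = FALSE)
  out <- ages[1] + full
  attr(out, "quadrature_error") <- err
  out
}

#' Unhealthy years of a curve set
#'
#' The area between the mortality and morbidity survival curves,
#' `integral (S_mortality - S_morbidity) = LE - HLE`: expected years lived
#' with disease. Negative pointwise gaps (flagged curve sets) make the result
#' carry `valid = FALSE`.
#'
#' @param curves An `ebmc_curve_set`.
#' @param when `"pre"` or `"post"`.
#' @return Years (scalar) with attribute `valid`.
#' @export
unhealthy_years <- function(curves, when = c("pre", "post")) {
  stopifnot(inherits(curves, "ebmc_curve_set"))
  when <- match.arg(when)
  row <- curves$summaries[curves$summaries$when == when, ]
  out <- row$unhealthy_years
  attr(out, "valid") <- row$valid
  out
}

#' Rectangularity summaries of a survival curve
#'
#' Interquartile range of the event-age distribution (smaller = more
#' rectangular; 0 for a degenerate step curve) and the magnitude of the
#' curve's slope at its median age.
#'
#' @inheritParams life_expectancy
#' @return List with `iqr_years` and `slope_at_median`.
#' @export
rectangularity <- function(ages, survival) {
  stopifnot(length(ages) == length(survival), all(diff(ages) > 0))
  age_at <- function(s_target) {
    below <- which(survival <= s_target)
    if (!length(below) || below[1] == 1) {
      stop("quartile of the event-age law lies outside the age grid", call. = FALSE)
    }
    i <- below[1]
    # linear interpolation between the bracketing grid points
    s1 <- survival[i - 1]; s2 <- survival[i]
    if (s1 == s2) return(ages[i])
    ages[i - 1] + (s1 - s_target) / (s1 - s2) * (ages[i] - ages[i - 1])
  }
  q75 <- age_at(0.75)  # first quartile of event age
  q50 <- age_at(0.50)
  q25 <- age_at(0.25)
  i <- which(survival <= 0.5)[1]
  slope <- abs((survival[i] - survival[i - 1]) / (ages[i] - ages[i - 1]))
  list(iqr_years = q25 - q75, slope_at_median = slope, median_age = q50)
}
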