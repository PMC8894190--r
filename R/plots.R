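# ggplot2 visualisations for the main result types.

#' Plot a scenario curve set
#'
#' Morbidity (dashed) and mortality (solid) survival curves before and after
#' the intervention, with the unhealthy-years area shaded for each state.
#'
#' @param object An `ebmc_curve_set` from [apply_scenario()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ebmc_curve_set
#' @export
autoplot.ebmc_curve_set <- function(object, ...) {
  long <- tidy(object) |>
    dplyr::mutate(when = factor(.data$when, levels = c("pre", "post")))
  ribbon <- object$curves |>
    dplyr::transmute(age = .data$age,
                     pre_lo = .data$S_morbidity_pre,
                     pre_hi = .data$S_mortality_pre,
                     post_lo = .data$S_morbidity_post,
                     post_hi = .data$S_mortality_post)
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(data = ribbon,
      ggplot2::aes(x = .data$age, ymin = .data$pre_lo, ymax = .data$pre_hi),
      fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_ribbon(data = ribbon,
      ggplot2::aes(x = .data$age, ymin = .data$post_lo, ymax = .data$post_hi),
      fill = "seagreen", alpha = 0.25) +
    ggplot2::geom_line(data = long,
      ggplot2::aes(x = .data$age, y = .data$survival,
                   colour = .data$when, linetype = .data$curve)) +
    ggplot2::scale_linetype_manual(values = c(morbidity = "dashed",
                                              mortality = "solid")) +
    ggplot2::labs(x = "age (years)", y = "survival",
                  colour = "state", linetype = "curve",
                  title = sprintf("intervention: %s", object$spec$intervention$type),
                  subtitle = "shaded areas = years lived with disease (pre blue, post green)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted mortality model against the Kaplan-Meier curve
#'
#' @param object An `ebmc_fit`.
#' @param data The censored sample the model was fitted to.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ebmc_fit
#' @export
autoplot.ebmc_fit <- function(object, data, ...) {
  d <- censored_sample(data)
  km <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  km_tbl <- tibble::tibble(age = km$time, survival = km$surv)
  ages <- seq(object$terminus, max(d$time), length.out = 400)
  fit_tbl <- tibble::tibble(age = ages,
                            survival = dist_survival(object$dist, ages))
  ggplot2::ggplot() +
    ggplot2::geom_step(data = km_tbl,
                       ggplot2::aes(x = .data$age, y = .data$survival),
                       colour = "grey40") +
    ggplot2::geom_line(data = fit_tbl,
                       ggplot2::aes(x = .data$age, y = .data$survival),
                       colour = "firebrick") +
    ggplot2::labs(x = "age (years)", y = "survival",
                  title = sprintf("%s fit (loglik %.1f)", object$family,
                                  object$loglik),
                  subtitle = "grey: Kaplan-Meier; red: fitted parametric survival") +
    ggplot2::theme_minimal()
}

#' Plot the incidence survival and hazard of a causal system
#'
#' @param object An `ebmc_incidence` from [system_incidence_survival()].
#' @param ages Optional age grid.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ebmc_incidence
#' @export
autoplot.ebmc_incidence <- function(object, ages = NULL, ...) {
  tbl <- tidy(object, ages = ages) |>
    tidyr::pivot_longer(c("survival", "hazard"), names_to = "channel") |>
    dplyr::filter(is.finite(.data$value))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = NULL) +
    ggplot2::theme_minimal()
}
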