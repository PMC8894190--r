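#' Gompertz-Weibull survival mixture
#'
#' The population survival is a mixture of *survival functions*,
#' `S(x) = p * S_G(x) + (1 - p) * S_W(x)`: a fraction `p` of the population
#' follows the Gompertz schedule (deaths through sufficient causes molded by
#' the declining force of natural selection) and a fraction `1 - p` follows
#' the Weibull schedule (deaths through sufficient causes containing
#' evolutionarily recent environmental factors). This is a mixture of
#' divergent subpopulations, not a mixture of hazards.
#'
#' The result is itself an `ebmc_dist` (family `"mixture"`), so every channel
#' ([dist_cdf()], [dist_hazard()], [dist_quantile()], [dist_sample()]) and
#' the likelihood machinery apply to it directly. [sample_mixture()]
#' additionally reports which component generated each draw.
#'
#' @param p Mixture weight on the Gompertz component, in `[0, 1]`.
#' @param gompertz A [dist_gompertz()].
#' @param weibull A [dist_weibull()].
#' @return An `ebmc_dist` of family `mixture`.
#' @examples
#' mp <- mixture_params(0.7, dist_gompertz(0.01, 0.11, 10),
#'                      dist_weibull(4e-6, 3, 10))
#' dist_survival(mp, c(40, 60, 80))
#' @export
mixture_params <- function(p, gompertz, weibull) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1,
            inherits(gompertz, "ebmc_dist_gompertz"),
            inherits(weibull, "ebmc_dist_weibull"))
  terminus <- min(dist_terminus(gompertz), dist_terminus(weibull))
  d <- new_dist("mixture", list(p = p, gompertz = gompertz, weibull = weibull,
                                terminus = terminus))
  class(d) <- c("mixture_params", class(d))
  d
}

#' @export
print.mixture_params <- function(x, ...) {
  p <- x$params
  cat(sprintf("<mixture_params> p = %.3f\n  gompertz: lam=%.4g theta=%.4g a=%g\n  weibull:  alpha=%.4g gamma=%.4g a=%g\n",
              p$p, p$gompertz$params$lam, p$gompertz$params$theta,
              p$gompertz$params$terminus, p$weibull$params$alpha,
              p$weibull$params$gamma, p$weibull$params$terminus))
  invisible(x)
}

mixture_channel <- function(d, x, channel) {
  p <- d$params
  sg <- dist_eval(p$gompertz, x, channel)
  sw <- dist_eval(p$weibull, x, channel)
  p$p * sg + (1 - p$p) * sw
}

#' @export
dist_cdf.mixture_params <- function(d, x) mixture_channel(d, x, "cdf")

#' @export
dist_survival.mixture_params <- function(d, x) mixture_channel(d, x, "survival")

#' @export
dist_pdf.mixture_params <- function(d, x) mixture_channel(d, x, "pdf")

#' @export
dist_hazard.mixture_params <- function(d, x) {
  S <- dist_survival(d, x)
  f <- dist_pdf(d, x)
  ifelse(x <= dist_terminus(d), 0, ifelse(S > 0, f / S, Inf))
}

#' @export
dist_quantile.mixture_params <- function(d, q) {
  if (any(q < 0 | q >= 1 | !is.finite(q))) stop("`q` must lie in [0, 1)", call. = FALSE)
  quantile_root(d, q)
}

#' Sample a mixture with component labels
#'
#' Draws each individual's component membership (Gompertz with probability
#' `p`) and then the event age from that component, so the draw carries the
#' latent subpopulation label.
#'
#' @param mp A [mixture_params()].
#' @inheritParams dist_sample
#' @return Tibble with columns `age` and `component`
#'   (`"gompertz"`/`"weibull"`).
#' @export
sample_mixture <- function(mp, n, seed = NULL) {
  stopifnot(inherits(mp, "mixture_params"), n >= 1)
  if (!is.null(seed)) return(withr::with_seed(seed, sample_mixture(mp, n)))
  z <- stats::runif(n) < mp$params$p
  age <- numeric(n)
  if (any(z)) age[z] <- dist_draw(mp$params$gompertz, sum(z))
  if (any(!z)) age[!z] <- dist_draw(mp$params$weibull, sum(!z))
  tibble::tibble(age = age, component = ifelse(z, "gompertz", "weibull"))
}
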