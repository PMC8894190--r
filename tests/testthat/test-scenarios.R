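test_that("life expectancy quadrature matches closed forms", {
  # exponential law on an effectively infinite horizon: LE = terminus + 1/rate
  ages <- seq(10, 10 + 200, by = 0.05)
  S <- exp(-0.1 * (ages - 10))
  expect_equal(life_expectancy(ages, S), 10 + 10, tolerance = 1e-3,
               ignore_attr = TRUE)
  # degenerate step at age T: LE = T
  step <- ifelse(ages <= 80, 1, 0)
  expect_equal(life_expectancy(ages, step), 80, tolerance = 0.06,
               ignore_attr = TRUE)
  # refined-grid oracle for a Gompertz curve
  g <- dist_gompertz(4e-5, 0.1, 10)
  coarse <- seq(10, 110, by = 0.1)
  fine <- seq(10, 110, by = 0.002)
  expect_equal(life_expectancy(coarse, dist_survival(g, coarse)),
               life_expectancy(fine, dist_survival(g, fine)),
               tolerance = 0.01, ignore_attr = TRUE)
  expect_warning(life_expectancy(seq(10, 110, by = 25),
                                 dist_survival(g, seq(10, 110, by = 25))),
                 "coarse")
})

test_that("rectangularity summaries behave under steps, shifts and mixing", {
  ages <- seq(10, 110, by = 0.02)
  step <- ifelse(ages <= 80, 1, 0)
  expect_equal(rectangularity(ages, step)$iqr_years, 0, tolerance = 0.05)
  g <- dist_gompertz(4e-5, 0.1, 10)
  r1 <- rectangularity(ages, dist_survival(g, ages))
  # shift invariance of the IQR
  g_shift <- dist_gompertz(4e-5, 0.1, 15)
  r2 <- rectangularity(ages, dist_survival(g_shift, ages))
  expect_equal(r1$iqr_years, r2$iqr_years, tolerance = 1e-6)
  expect_equal(r2$median_age, r1$median_age + 5, tolerance = 1e-6)
  # pure Gompertz is more rectangular than a mixture spreading deaths earlier
  mix <- default_scenario()$mortality
  r_mix <- rectangularity(ages, dist_survival(mix, ages))
  expect_lt(r1$iqr_years, r_mix$iqr_years)
})

test_that("identity intervention reproduces the baseline bitwise", {
  cs <- apply_scenario(default_scenario())
  expect_identical(cs$curves$S_morbidity_pre, cs$curves$S_morbidity_post)
  expect_identical(cs$curves$S_mortality_pre, cs$curves$S_mortality_post)
  expect_true(cs$valid)
  # conservation: LE = HLE + unhealthy years under the same quadrature
  expect_equal(cs$summaries$LE, cs$summaries$HLE + cs$summaries$unhealthy_years)
})

test_that("complete EREF elimination yields the pure-Gompertz rectangularized curve", {
  cs <- apply_scenario(default_scenario(intervention_health_promotion(1)))
  gomp <- default_scenario()$mortality$params$gompertz
  expect_lt(max(abs(cs$curves$S_mortality_post -
                      dist_survival(gomp, cs$curves$age))), 1e-10)
})

test_that("scenario orderings match the qualitative healthy-aging claims", {
  base <- apply_scenario(default_scenario())
  hp <- apply_scenario(default_scenario(intervention_health_promotion(0.5)))
  pa <- apply_scenario(default_scenario(intervention_postponed_aging(shift_years = 5)))
  cb <- apply_scenario(default_scenario(intervention_combined(
    intervention_health_promotion(0.5),
    intervention_postponed_aging(shift_years = 5))))
  gain <- function(cs) cs$summaries$LE[2] - cs$summaries$LE[1]
  d_uy <- function(cs) unhealthy_years(cs, "post") - unhealthy_years(cs, "pre")
  # health promotion: longer life AND fewer unhealthy years
  expect_gt(gain(hp), 0)
  expect_lt(d_uy(hp), 0)
  # postponed aging with an equal shift: longer life, unhealthy years unchanged
  expect_gt(gain(pa), 0)
  expect_lt(abs(d_uy(pa)), 0.05)
  # combined: at least the gain of each single intervention
  expect_gte(gain(cb), gain(hp) - 1e-9)
  expect_gte(gain(cb), gain(pa) - 1e-9)
})

test_that("unhealthy years vanish for equal curves and equal a pure time shift", {
  mp <- default_scenario()$mortality
  spec_eq <- scenario_spec(mp, mp)
  cs_eq <- apply_scenario(spec_eq)
  expect_equal(unhealthy_years(cs_eq, "pre"), 0, ignore_attr = TRUE)
  # morbidity = mortality shifted left by d years: area between curves ~ d
  d_shift <- 4
  g <- mp$params$gompertz$params
  w <- mp$params$weibull$params
  morb_shift <- mixture_params(mp$params$p,
    dist_gompertz(g$lam, g$theta, g$terminus - d_shift),
    dist_weibull(w$alpha, w$gamma, w$terminus - d_shift))
  # evaluate on a grid starting at the morbidity terminus to keep S valid
  spec_sh <- scenario_spec(morb_shift, mp, horizon = 130, step = 0.05)
  cs_sh <- apply_scenario(spec_sh)
  expect_equal(unhealthy_years(cs_sh, "pre"), d_shift, tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("ordering violations are flagged rather than silently summarised", {
  mp <- default_scenario()$mortality
  late_morb <- mixture_params(mp$params$p,
    dist_gompertz(mp$params$gompertz$params$lam / 4, 0.1, 10),
    mp$params$weibull)
  expect_warning(cs <- apply_scenario(scenario_spec(late_morb, mp)),
                 "morbidity")
  expect_false(cs$valid)
  expect_false(attr(unhealthy_years(cs, "pre"), "valid"))
})

test_that("life expectancy responds monotonically to theta and the Weibull weight", {
  le_of <- function(p, theta) {
    mp <- mixture_params(p, dist_gompertz(4e-5, theta, 10),
                         dist_weibull(7.2e-10, 5, 10))
    ages <- seq(10, 110, by = 0.1)
    life_expectancy(ages, dist_survival(mp, ages))
  }
  thetas <- c(0.08, 0.1, 0.12, 0.15)
  les_theta <- vapply(thetas, function(th) le_of(0.8, th), numeric(1))
  expect_true(all(diff(les_theta) < 0))  # faster aging, shorter life
  ps <- c(0.5, 0.65, 0.8, 0.95)
  les_p <- vapply(ps, function(p) le_of(p, 0.1), numeric(1))
  expect_true(all(diff(les_p) > 0))      # more Weibull weight, shorter life
})
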