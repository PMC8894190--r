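test_that("censored log-likelihood matches closed forms and degenerate cases", {
  # single event at t under the exponential law: log(lam) - lam * (t - a)
  d1 <- data.frame(time = 17, event = 1)
  expect_equal(loglik_censored(d1, exp_dist(0.2, 10)),
               log(0.2) - 0.2 * 7)
  # mixture with p = 1 collapses to the pure Gompertz likelihood
  g <- dist_gompertz(0.02, 0.1, 10)
  mp1 <- mixture_params(1, g, dist_weibull(1e-6, 3, 10))
  d <- data.frame(time = c(40, 55, 70, 80), event = c(1, 1, 0, 1))
  expect_equal(loglik_censored(d, mp1), loglik_censored(d, g))
  # left-truncation correction: subtract log S(entry)
  de <- data.frame(time = 60, event = 1, entry = 40)
  expect_equal(loglik_censored(de, g),
               log(dist_pdf(g, 60)) - log(dist_survival(g, 40)))
  expect_error(loglik_censored(data.frame(time = 5, event = 1), g), "terminus")
})

test_that("analytic likelihood equals a quadrature/finite-difference oracle", {
  withr::with_seed(41, {
    for (rep in 1:25) {
      fam <- sample(c("gompertz", "weibull", "makeham", "mixture"), 1)
      model <- switch(fam,
        gompertz = dist_gompertz(runif(1, 0.005, 0.05), runif(1, 0.02, 0.15), 10),
        weibull = dist_weibull(10^runif(1, -7, -3), runif(1, 1.5, 4), 10),
        makeham = dist_makeham(runif(1, 0.005, 0.05), runif(1, 0.02, 0.15),
                               runif(1, 0.001, 0.01), 10),
        mixture = mixture_params(runif(1, 0.2, 0.8),
                                 dist_gompertz(runif(1, 0.005, 0.05),
                                               runif(1, 0.02, 0.15), 10),
                                 dist_weibull(10^runif(1, -7, -3),
                                              runif(1, 1.5, 4), 10)))
      t_ev <- dist_quantile(model, runif(1, 0.1, 0.9))
      t_ce <- dist_quantile(model, runif(1, 0.1, 0.9))
      d <- data.frame(time = c(t_ev, t_ce), event = c(1, 0))
      # oracle: density from central differences of the cdf, survival from
      # integrating the density over the upper tail
      h <- 1e-5
      f_num <- (dist_cdf(model, t_ev + h) - dist_cdf(model, t_ev - h)) / (2 * h)
      S_num <- 1 - (dist_cdf(model, 10) +
                      integrate(function(x) dist_pdf(model, x), 10, t_ce,
                                rel.tol = 1e-12, abs.tol = 1e-14)$value)
      oracle <- log(f_num) + log(S_num)
      expect_equal(loglik_censored(d, model), oracle, tolerance = 1e-6)
    }
  })
})

test_that("likelihood values agree with the flexsurv reference implementation", {
  skip_if_not_installed("flexsurv")
  g <- dist_gompertz(0.02, 0.1, 0)
  xs <- c(10, 25, 40)
  expect_equal(dist_pdf(g, xs), flexsurv::dgompertz(xs, shape = 0.1, rate = 0.02),
               tolerance = 1e-12)
  expect_equal(dist_survival(g, xs),
               1 - flexsurv::pgompertz(xs, shape = 0.1, rate = 0.02),
               tolerance = 1e-12)
})

test_that("Gompertz parameters are recovered within sampling error under censoring", {
  true <- dist_gompertz(0.02, 0.1, 10)
  withr::with_seed(42, {
    ages <- dist_sample(true, 1e4)
    cens <- runif(1e4) < 0.1
    time <- ifelse(cens, pmax(10, ages * runif(1e4)), ages)
    d <- data.frame(time = time, event = as.integer(!cens))
  })
  fit <- fit_mortality(d, "gompertz", terminus = 10, n_starts = 4, seed = 1)
  expect_true(fit$converged)
  est <- fit$estimates
  expect_lt(abs(est$estimate[est$term == "lam"] - 0.02),
            3 * est$std.error[est$term == "lam"])
  expect_lt(abs(est$estimate[est$term == "theta"] - 0.1),
            3 * est$std.error[est$term == "theta"])
})

test_that("Weibull fit on exactly-Weibull minima recovers the generating shape", {
  cv <- convergence_to_limit(dist_weibull(0.001, 2.8, 10), n_causes = 30,
                             n_reps = 5000, seed = 5)
  gam_hat <- cv$fitted_limit$estimates$estimate[2]
  expect_lt(abs(gam_hat - 2.8) / 2.8, 0.05)
})

test_that("Weibull MLE agrees with survival::survreg on censored data", {
  w <- dist_weibull(2e-4, 2, 10)
  withr::with_seed(43, {
    ages <- dist_sample(w, 5000)
    cens_at <- 75
    d <- data.frame(time = pmin(ages, cens_at),
                    event = as.integer(ages <= cens_at))
  })
  fit <- fit_mortality(d, "weibull", terminus = 10, n_starts = 3, seed = 1)
  sr <- survival::survreg(survival::Surv(time - 10, event) ~ 1, data = d,
                          dist = "weibull")
  gamma_sr <- 1 / sr$scale
  alpha_sr <- exp(-coef(sr)[[1]] * gamma_sr)
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  expect_equal(est[["gamma"]], gamma_sr, tolerance = 1e-3)
  expect_equal(est[["alpha"]], alpha_sr, tolerance = 1e-2)
})

test_that("censoring at the terminus leaves the MLE unchanged and models nest", {
  d <- data.frame(time = dist_sample(dist_gompertz(0.02, 0.1, 10), 3000, seed = 6),
                  event = 1)
  f1 <- fit_mortality(d, "gompertz", terminus = 10, n_starts = 2, seed = 1)
  d_aug <- rbind(d, data.frame(time = rep(10, 100), event = 0))
  f2 <- fit_mortality(d_aug, "gompertz", terminus = 10, n_starts = 2, seed = 1)
  expect_equal(f1$estimates$estimate, f2$estimates$estimate, tolerance = 1e-8)
  # nesting: the mixture's maximised loglik is never below the pure fit's
  fm <- fit_mortality(d, "mixture", terminus = 10, n_starts = 4, seed = 1)
  expect_gte(fm$loglik, f1$loglik - 1e-6)
})

test_that("fit comparison ranks models and refuses mixed data sets", {
  mp <- spec_mixture()
  coh <- generate_cohort(mp, 6000, admin_censor_age = 75, seed = 7)
  fg <- fit_mortality(coh, "gompertz", terminus = 10, n_starts = 3, seed = 1)
  fw <- fit_mortality(coh, "weibull", terminus = 10, n_starts = 3, seed = 1)
  fm <- fit_mortality(coh, "mixture", terminus = 10, n_starts = 5, seed = 1)
  cmp <- compare_fits(fg, fw, fm)
  expect_equal(nrow(cmp), 3)
  expect_equal(cmp$family[1], "mixture")  # well-separated mixture wins
  expect_equal(cmp$delta_AIC[1], 0)
  expect_equal(nrow(compare_fits(fg)), 1)
  other <- generate_cohort(mp, 500, seed = 8)
  fo <- fit_mortality(other, "gompertz", terminus = 10, n_starts = 2, seed = 1)
  expect_error(compare_fits(fg, fo), "different data")
})

test_that("tidy and glance expose broom-style summaries", {
  d <- data.frame(time = dist_sample(dist_gompertz(0.02, 0.1, 10), 2000, seed = 9),
                  event = 1)
  fit <- fit_mortality(d, "gompertz", terminus = 10, n_starts = 2, seed = 1)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  gl <- glance(fit)
  expect_equal(gl$df, 2)
  expect_equal(gl$AIC, 2 * 2 - 2 * fit$loglik)
  expect_true(gl$converged)
  # unfittable cases error early
  expect_error(suppressWarnings(
    fit_mortality(data.frame(time = c(50, 60), event = 0), "gompertz")),
    "censored")
})
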