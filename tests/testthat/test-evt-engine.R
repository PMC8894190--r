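test_that("max_cdf and min_survival implement the exact product formulas", {
  unif <- function(x) pmin(pmax(x, 0), 1)
  expect_equal(max_cdf(list(unif, unif))(0.5), 0.25)
  # single element: identity
  g <- dist_gompertz(0.01, 0.1, 10)
  xs <- seq(10, 90, length.out = 100)
  expect_equal(max_cdf(list(function(x) dist_cdf(g, x)))(xs), dist_cdf(g, xs))
  expect_error(max_cdf(list()), "non-empty")
  expect_error(min_survival(list()), "non-empty")
  # min of n iid exponentials is exponential with rate n*r (exact identity)
  r <- 0.3; n <- 7
  Smin <- min_survival(rep(list(function(x) dist_survival(exp_dist(r), x)), n))
  expect_lt(max(abs(Smin(xs) - dist_survival(exp_dist(n * r), xs))), 1e-12)
  # min of n iid Weibulls is Weibull with scale-rate n*alpha, same shape
  w <- dist_weibull(0.002, 2.5, 10)
  Swmin <- min_survival(rep(list(function(x) dist_survival(w, x)), 4))
  expect_lt(max(abs(Swmin(xs) - dist_survival(dist_weibull(0.008, 2.5, 10), xs))),
            1e-12)
  # Monte-Carlo oracle for a max of three distinct Weibulls
  ws <- list(dist_weibull(0.01, 1.5, 0), dist_weibull(0.002, 2.5, 0),
             dist_weibull(5e-4, 3, 0))
  Fmax <- max_cdf(lapply(ws, function(d) function(x) dist_cdf(d, x)))
  sims <- withr::with_seed(31, {
    do.call(pmax, lapply(ws, function(d) dist_sample(d, 1e5)))
  })
  expect_lt(ks_distance(sims, Fmax), 0.01)
})

test_that("system incidence survival matches closed forms and drops excluded causes", {
  # single cause, single component: population survival is the truncated law
  g <- dist_lognormal(3.5, 0.4, 10)
  sys1 <- causal_system(list(component_cause("g1", "LOGE", g)),
                        list(sufficient_cause("s1", "g1")))
  inc1 <- system_incidence_survival(sys1)
  xs <- seq(10, 100, length.out = 200)
  expect_equal(inc1$survival(xs), dist_survival(g, xs), tolerance = 1e-12)
  # two disjoint exponential causes: rates add after the terminus
  sys2 <- causal_system(
    list(component_cause("a", "LOGE", dist_lognormal(3, 0.5, 10)),
         component_cause("b", "LOGE", dist_lognormal(3.5, 0.5, 10))),
    list(sufficient_cause("s1", "a"), sufficient_cause("s2", "b")))
  inc2 <- system_incidence_survival(sys2)
  Sa <- function(x) dist_survival(sys2$components$timing[[1]], x)
  Sb <- function(x) dist_survival(sys2$components$timing[[2]], x)
  expect_equal(inc2$survival(xs), Sa(xs) * Sb(xs), tolerance = 1e-12)
  expect_equal(inc2$n_causes_used, 2)
  # excluded-type causes are dropped with a warning and counted
  sys3 <- causal_system(
    list(component_cause("g1", "LOGE", dist_lognormal(3.5, 0.4, 10)),
         component_cause("e1", "EOGE", dist_gamma(2, 1, 0))),
    list(sufficient_cause("s1", "g1"), sufficient_cause("s2", "e1")))
  expect_warning(inc3 <- system_incidence_survival(sys3), "excluded")
  expect_equal(inc3$n_causes_used, 1)
  expect_equal(inc3$n_excluded, 1)
})

test_that("simulation honours the max rule, sharing ties, and the product oracle", {
  # degenerate components: completion at the max (50)
  sys <- causal_system(
    list(component_cause("c30", "LOGE", dist_fixed(30)),
         component_cause("c50", "LOGE", dist_fixed(50))),
    list(sufficient_cause("s1", c("c30", "c50"))))
  ev <- simulate_first_event(sys, 100, seed = 1)
  expect_true(all(ev$event_age == 50))
  # full sharing: identical completions, tie broken to the smallest cause id
  sys_tie <- causal_system(
    list(component_cause("c1", "LOGE", dist_lognormal(3.5, 0.4, 10))),
    list(sufficient_cause("s_b", "c1"), sufficient_cause("s_a", "c1")))
  ev_tie <- simulate_first_event(sys_tie, 500, seed = 2)
  expect_true(all(ev_tie$cause_id == "s_a"))
  expect_equal(attr(ev_tie, "tie_fraction"), 1)
  # determinism
  expect_identical(simulate_first_event(two_cause_system(), 100, seed = 9),
                   simulate_first_event(two_cause_system(), 100, seed = 9))
  # no sharing: empirical law matches the analytic product formula
  sys2 <- two_cause_system()
  inc <- system_incidence_survival(sys2)
  sim <- simulate_first_event(sys2, 1e5, seed = 3)
  expect_lt(ks_distance(sim$event_age, function(x) 1 - inc$survival(x)), 0.01)
})

test_that("shared components make simulated minima dominate the independent product", {
  sys <- shared_system()
  inc <- suppressWarnings(system_incidence_survival(sys))
  expect_true(inc$shared_components_ignored)
  sim <- simulate_first_event(sys, 5e4, seed = 4)
  xs <- quantile(sim$event_age, seq(0.05, 0.95, by = 0.05))
  S_emp <- 1 - ecdf(sim$event_age)(xs)
  S_prod <- inc$survival(xs)
  # dependence direction: simulated survival >= independent product (up to MC noise)
  expect_true(all(S_emp >= S_prod - 0.01))
  expect_gt(max(S_emp - S_prod), 0.02)  # the gap is real for this system
})

test_that("cause-completion survival is stochastically increasing in component count", {
  # iid components: survival of the max, 1 - F^k, is nondecreasing in k
  d <- dist_lognormal(3.5, 0.4, 10)
  xs <- seq(11, 100, length.out = 200)
  Fx <- dist_cdf(d, xs)
  for (k in 1:4) {
    expect_true(all(1 - Fx^(k + 1) >= 1 - Fx^k - 1e-15))
  }
})

test_that("incidence hazard of a default molded system is nondecreasing", {
  sys <- causal_system(
    list(component_cause("g1", "LOGE", dist_lognormal(3.6, 0.35, 10)),
         component_cause("g2", "LOGE", dist_lognormal(3.9, 0.3, 10)),
         component_cause("g3", "LOGE", dist_lognormal(4.1, 0.25, 10))),
    list(sufficient_cause("s1", "g1"), sufficient_cause("s2", c("g1", "g2")),
         sufficient_cause("s3", c("g2", "g3"))))
  tbl <- tidy(system_incidence_survival(sys),
              ages = seq(15, 80, length.out = 300))
  h <- tbl$hazard[is.finite(tbl$hazard)]
  expect_true(all(diff(h) > -1e-9))
})

test_that("convergence experiment predicts the right limit and tracks closures", {
  # Weibull initial law: minima are exactly Weibull, KS at the sampling floor
  cvw <- convergence_to_limit(dist_weibull(0.002, 2.5, 10), n_causes = 50,
                              n_reps = 4000, seed = 11)
  expect_equal(cvw$domain_predicted, "weibull_domain")
  expect_lt(cvw$ks_distance, 1.5 * 1.36 / sqrt(4000))
  # fitted shape matches the generating shape (closure property)
  gam_hat <- cvw$fitted_limit$estimates$estimate[2]
  expect_lt(abs(gam_hat - 2.5) / 2.5, 0.05)
  # n_causes = 1: minima reproduce the initial law itself
  cv1 <- convergence_to_limit(dist_weibull(0.002, 2.5, 10), n_causes = 1,
                              n_reps = 4000, seed = 12)
  expect_lt(cv1$ks_distance, 1.5 * 1.36 / sqrt(4000))
  # flat initial law heads to the Gompertz limit
  cvf <- convergence_to_limit(dist_flat(5, 10), n_causes = 100,
                              n_reps = 4000, seed = 13)
  expect_equal(cvf$domain_predicted, "gompertz_domain")
  expect_equal(cvf$fitted_limit$family, "gompertz")
})
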