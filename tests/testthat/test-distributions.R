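test_that("closed-form channel values match hand calculations", {
  g <- dist_gompertz(0.01, 0.1, 10)
  expect_equal(dist_hazard(g, 10), 0.01)
  expect_equal(dist_hazard(g, 20), 0.01 * exp(1))
  # gamma = 1 Weibull is the constant-hazard exponential
  w1 <- dist_weibull(1, 1, 0)
  expect_equal(dist_hazard(w1, c(0.5, 2, 7)), rep(1, 3))
  expect_equal(dist_cdf(dist_flat(1, 0), 1), exp(-1))
  # below the terminus: F = 0, S = 1, f = 0, h = 0
  for (d in list(g, dist_weibull(2, 3, 10), dist_flat(1, 10),
                 dist_makeham(0.01, 0.1, 0.002, 10),
                 dist_lognormal(3, 0.5, 10), dist_gamma(2, 1, 10))) {
    expect_equal(dist_cdf(d, c(0, 9.99)), c(0, 0))
    expect_equal(dist_survival(d, c(0, 9.99)), c(1, 1))
    expect_equal(dist_pdf(d, c(0, 9.99)), c(0, 0))
    expect_equal(dist_hazard(d, c(0, 9.99)), c(0, 0))
  }
})

test_that("quantile inverts the cdf across families", {
  expect_equal(dist_quantile(dist_weibull(1, 2, 0), 1 - exp(-1)), 1)
  fams <- list(dist_gompertz(0.01, 0.1, 10), dist_weibull(0.002, 2.5, 10),
               dist_makeham(0.01, 0.08, 0.003, 10), dist_flat(2, 10),
               dist_regvar(0.04, 1.5, 10), dist_lognormal(3.4, 0.4, 10),
               dist_gamma(3, 0.2, 10),
               dist_threshold(dist_lognormal(3, 0.3), dist_gamma(4, 4),
                              dist_lognormal(3.4, 0.5)))
  withr::with_seed(11, {
    u <- runif(200)
    for (d in fams) {
      expect_lt(max(abs(dist_cdf(d, dist_quantile(d, u)) - u)), 1e-8)
      expect_equal(dist_quantile(d, 0), d$params$terminus)
    }
  })
  expect_error(dist_quantile(dist_flat(1), 1), "0, 1")
  expect_error(dist_quantile(dist_flat(1), -0.1), "0, 1")
})

test_that("channels are mutually consistent (f integrates to F, h = f/S)", {
  fams <- list(dist_gompertz(0.02, 0.1, 10), dist_weibull(0.002, 2.5, 10),
               dist_makeham(0.01, 0.08, 0.003, 10), dist_flat(2, 10),
               dist_lognormal(3.4, 0.4, 10), dist_gamma(3, 0.2, 10))
  for (d in fams) {
    a <- d$params$terminus
    for (x in a + c(5, 20, 60)) {
      Fq <- integrate(function(t) dist_pdf(d, t), a, x,
                      rel.tol = 1e-10, abs.tol = 1e-12)$value
      expect_lt(abs(Fq - dist_cdf(d, x)), 1e-6)
    }
    xs <- a + c(1, 10, 40)
    S <- dist_survival(d, xs)
    keep <- S > 1e-12
    expect_equal(dist_hazard(d, xs)[keep],
                 (dist_pdf(d, xs) / S)[keep], tolerance = 1e-10)
  }
})

test_that("theta = 0 Gompertz and gamma = 1 Weibull equal the exponential law", {
  xs <- seq(0, 50, length.out = 201)
  e1 <- dist_gompertz(0.05, 0, 0)
  e2 <- dist_weibull(0.05, 1, 0)
  expect_lt(max(abs(dist_cdf(e1, xs) - pexp(xs, 0.05))), 1e-12)
  expect_lt(max(abs(dist_cdf(e2, xs) - pexp(xs, 0.05))), 1e-12)
})

test_that("seeded sampling is reproducible and matches the analytic cdf", {
  d <- dist_gompertz(0.01, 0.1, 10)
  expect_identical(dist_sample(d, 100, seed = 42), dist_sample(d, 100, seed = 42))
  fams <- list(gompertz = d, weibull = dist_weibull(0.002, 2.5, 10),
               flat = dist_flat(1, 10), regvar = dist_regvar(0.04, 1.5, 10),
               lognormal = dist_lognormal(3.4, 0.4, 10))
  for (nm in names(fams)) {
    s <- dist_sample(fams[[nm]], 1e5, seed = 5)
    expect_lt(ks_distance(s, function(x) dist_cdf(fams[[nm]], x)), 0.01)
  }
  # support bound of the flat family
  expect_gt(min(dist_sample(dist_flat(1, 10), 1e5, seed = 6)), 10)
})

test_that("threshold-exposure sampling composes onset + threshold/rate", {
  thr <- dist_threshold(dist_fixed(0), dist_fixed(1), dist_fixed(5))
  expect_equal(dist_sample(thr, 20, seed = 1), rep(5, 20))
  # doubling a degenerate threshold doubles every sample
  t1 <- dist_threshold(dist_fixed(0), dist_fixed(1), dist_fixed(4))
  t2 <- dist_threshold(dist_fixed(0), dist_fixed(1), dist_fixed(8))
  expect_equal(dist_sample(t2, 50, seed = 2), 2 * dist_sample(t1, 50, seed = 2))
  # stochastically larger threshold law shifts the empirical cdf right
  lo <- dist_threshold(dist_fixed(20), dist_gamma(4, 4), dist_lognormal(3.0, 0.4))
  hi <- dist_threshold(dist_fixed(20), dist_gamma(4, 4), dist_lognormal(3.6, 0.4))
  s_lo <- sort(dist_sample(lo, 1e5, seed = 3))
  s_hi <- sort(dist_sample(hi, 1e5, seed = 3))
  qs <- quantile(s_lo, c(0.1, 0.25, 0.5, 0.75, 0.9))
  expect_true(all(ecdf(s_hi)(qs) < ecdf(s_lo)(qs)))
  # quadrature cdf agrees with Monte-Carlo
  expect_lt(max(abs(dist_cdf(lo, qs) - ecdf(s_lo)(qs))), 0.01)
})

test_that("unimodality check accepts shifted lognormal/gamma and rejects a bimodal law", {
  expect_true(is_unimodal(dist_lognormal(3.5, 0.4, 10)))
  expect_true(is_unimodal(dist_gamma(3, 0.2, 10)))
  # a survival mixture with well-separated components has a bimodal density
  bimodal <- mixture_params(0.5, dist_gompertz(0.2, 0.3, 0),
                            dist_weibull(50^-8, 8, 0))
  expect_false(is_unimodal(bimodal))
})
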