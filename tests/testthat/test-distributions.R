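test_that("negative binomial pmf matches closed forms and the Poisson limit", {
  # r = 0: (1 + theta*mean)^(-1/theta)
  expect_equal(nb_pmf(0, mean = 2, dispersion = 0.5), 0.25)
  # theta = 1, mean = 1: geometric with p = 1/2
  expect_equal(nb_pmf(1, mean = 1, dispersion = 1), 0.25)
  # exact Poisson branch at theta = 0
  expect_equal(nb_pmf(3, mean = 1.7, dispersion = 0),
               exp(-1.7) * 1.7^3 / factorial(3))
  # continuity: theta = 1e-8 approaches the Poisson pmf
  expect_equal(nb_pmf(3, mean = 1.7, dispersion = 1e-8),
               dpois(3, 1.7), tolerance = 1e-6)
  # pointwise convergence at theta = 1e-6, sup-norm over a wide support
  r <- 0:60
  expect_lt(max(abs(nb_pmf(r, mean = 5, dispersion = 1e-6) -
                      dpois(r, 5))), 1e-4)
})

test_that("nb pmf normalises and has mean equal to its mean parameter", {
  r <- 0:10000
  for (cfg in list(c(2, 0.5), c(10, 3), c(0.5, 8))) {
    p <- nb_pmf(r, mean = cfg[1], dispersion = cfg[2])
    expect_equal(sum(p), 1, tolerance = 1e-8)
    expect_equal(sum(r * p), cfg[1], tolerance = 1e-6)
  }
})

test_that("nb pmf rejects invalid arguments", {
  expect_error(nb_pmf(-1, 1, 1), "non-negative")
  expect_error(nb_pmf(1, -2, 1), "positive")
  expect_error(nb_pmf(1, 1, -0.1), "non-negative")
})

test_that("truncated nb pmf renormalises over the remaining capacity", {
  # normalisation for assorted (mean, dispersion, upper)
  for (cfg in list(list(1, 0.5, 5), list(4, 8, 28), list(0.2, 0, 16))) {
    p <- truncated_nb_pmf(0:cfg[[3]], cfg[[1]], cfg[[2]], cfg[[3]])
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  # direct finite-sum oracle
  num <- nb_pmf(2, 1, 0.5)
  den <- sum(nb_pmf(0:5, 1, 0.5))
  expect_equal(truncated_nb_pmf(2, 1, 0.5, 5), num / den)
  # saturated area: point mass at zero
  expect_equal(truncated_nb_pmf(0, 3, 2, upper = 0), 1)
  # truncation preserves probability ratios
  expect_equal(truncated_nb_pmf(3, 2, 1, 6) / truncated_nb_pmf(1, 2, 1, 6),
               nb_pmf(3, 2, 1) / nb_pmf(1, 2, 1))
  expect_error(truncated_nb_pmf(7, 2, 1, 6), "exceeds")
})

test_that("the compiled truncated log-pmf agrees with the dnbinom route", {
  cfgs <- expand.grid(d = 0:4, lam = c(0.05, 0.8, 3.7, 25),
                      theta = c(0, 1e-3, 0.7, 8, 13), upper = c(4, 16, 28))
  for (i in seq_len(nrow(cfgs))) with(cfgs[i, ], {
    got <- moverstayer:::cpp_trunc_nb_logpmf(as.integer(d), lam, theta,
                                             as.integer(upper))
    want <- truncated_nb_pmf(d, lam, theta, upper, log = TRUE)
    expect_equal(got, want, tolerance = 1e-12)
  })
  # log-space fallback for extreme means
  expect_equal(moverstayer:::cpp_trunc_nb_logpmf(28L, 1e12, 0.5, 28L),
               truncated_nb_pmf(28, 1e12, 0.5, 28, log = TRUE),
               tolerance = 1e-9)
})

test_that("interval intensity multiplies time, baseline and covariates", {
  p0 <- list(lambda0 = 0.15, beta = c(0, 0, 0))
  expect_equal(interval_intensity(0.5, c(0, 0, 0), p0), 0.075)
  p1 <- list(lambda0 = 0.37, beta = c(0.1, 0, 0))
  expect_equal(interval_intensity(1, c(3, 0, 0), p1), 0.37 * exp(0.3))
  # proportional in interval length
  expect_equal(interval_intensity(1, c(2, 1, 0), p1),
               interval_intensity(0.5, c(2, 1, 0), p1) * 2)
  # configured extra covariate must be supplied by name
  p2 <- list(lambda0 = 0.2, beta = c(active_hands = 0.11, h = 0, f = 0,
                                     l = 0))
  expect_equal(interval_intensity(1, c(0, 0, 0), p2,
                                  covariates = c(active_hands = 2)),
               0.2 * exp(0.22))
  expect_error(interval_intensity(1, c(0, 0, 0), p2), "covariates")
  expect_error(interval_intensity(1, c(0, 0, 0), p2,
                                  covariates = c(other = 1)), "missing")
})

test_that("pre-clinic distribution is a capacity-truncated NB with a degenerate limit", {
  expect_equal(preclinic_prob(0, 0, 0.65, 4.7, 28), 1)
  expect_equal(preclinic_prob(3, 0, 0.65, 4.7, 28), 0)
  p <- preclinic_prob(0:28, 2, 0.65, 4.7, 28)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # 29-term sum oracle
  want <- nb_pmf(1, 2 * 0.65, 4.7) / sum(nb_pmf(0:28, 2 * 0.65, 4.7))
  expect_equal(preclinic_prob(1, 2, 0.65, 4.7, 28), want)
  expect_error(preclinic_prob(29, 2, 0.65, 4.7, 28), "capacity")
})

test_that("frailty Laplace transforms match their closed forms and densities", {
  s <- c(0, 0.3, 2, 11)
  expect_equal(frailty_laplace(s, 3.9, "gamma"), (1 + 3.9 * s)^(-1 / 3.9))
  expect_equal(frailty_laplace(0, 2, "invgauss"), 1)
  # against direct integration of the unit-mean IG density
  for (si in c(0.5, 4)) {
    want <- stats::integrate(function(v) exp(-si * v) *
                               dinvgauss_unit(v, 2), 0, Inf,
                             rel.tol = 1e-10)$value
    expect_equal(frailty_laplace(si, 2, "invgauss"), want,
                 tolerance = 1e-8)
  }
})
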