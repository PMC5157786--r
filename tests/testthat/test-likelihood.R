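test_that("area path probabilities multiply increment and pre-clinic terms", {
  prm <- toy_params(preclinic = TRUE)
  # single visit, entry at onset, no damage: empty product, degenerate
  # pre-clinic term
  s1 <- area_summaries(toy_data(cbind(0, 0, 0)), prm, ms_model())
  expect_equal(unname(s1$path_prob[1, ]), c(1, 1, 1))
  expect_equal(unname(s1$ever_damaged[1, ]), c(0L, 0L, 0L))

  # all-zero path over 2 intervals with a pre-clinic gap: direct product
  dat <- toy_data(matrix(0, 3, 3), onset_gap = 2)
  s <- area_summaries(dat, prm, ms_model())
  for (a in 1:3) {
    lam <- 0.5 * prm$lambda0[[a]]
    caps <- c(28, 20, 16)[a]
    want <- truncated_nb_pmf(0, lam, prm$theta[[a]], caps)^2 *
      preclinic_prob(0, 2, prm$lambda0_pre[[a]], prm$theta_pre[[a]], caps)
    expect_equal(unname(s$path_prob[1, a]), want, tolerance = 1e-12)
  }

  # a damaged path: product of truncated pmfs with shifting bounds and
  # dynamic covariates (hand damage feeds the hand intensity here)
  prm2 <- toy_params(beta_diag = c(0.2, 0, 0))
  dat2 <- toy_data(cbind(c(0, 2, 3), c(0, 0, 0), c(0, 0, 0)))
  s2 <- area_summaries(dat2, prm2, ms_model())
  l1 <- 0.5 * prm2$lambda0[[1]]            # counts (0,0,0) at interval 1
  l2 <- 0.5 * prm2$lambda0[[1]] * exp(0.4) # hand count 2 at interval 2
  want <- truncated_nb_pmf(2, l1, 8, 28) * truncated_nb_pmf(1, l2, 8, 26)
  expect_equal(unname(s2$path_prob[1, 1]), want, tolerance = 1e-12)
  expect_equal(unname(s2$ever_damaged[1, ]), c(1L, 0L, 0L))

  # probabilities are in (0, 1] on simulated data
  sim <- simulate_ms(sim_design(40, n_visits = 6), seed = 3)
  ss <- area_summaries(sim, toy_params(), ms_model())
  expect_true(all(ss$path_prob > 0 & ss$path_prob <= 1))
})

test_that("conditional likelihood combines stayer and mover factors", {
  P <- c(0.2, 0.5, 0.9); om <- c(1.2, 0.8, 0.5)
  # all areas damaged: plain product e^{-u omega} P
  expect_equal(conditional_patient_lik(P, c(1, 1, 1), om, 2),
               prod(exp(-2 * om) * P))
  # never-damaged factors tend to 1 as u grows (certain stayer)
  expect_equal(conditional_patient_lik(P, c(0, 0, 0), om, 1e8),
               1, tolerance = 1e-12)
  # mixed case against term-by-term assembly
  cs <- c(1, 0, 0)
  want <- exp(-2 * om[1]) * P[1] *
    (1 - exp(-2 * om[2]) * (1 - P[2])) *
    (1 - exp(-2 * om[3]) * (1 - P[3]))
  expect_equal(conditional_patient_lik(P, cs, om, 2), want)
})

test_that("sign expansion equals frailty quadrature across random configurations", {
  set.seed(41)
  for (rep in 1:80) {
    P <- runif(3)
    cs <- rbinom(3, 1, 0.5)
    om <- exp(runif(3, -2, 1))
    gam <- runif(1, 0.2, 6)
    fam <- if (rep %% 4 == 0) "invgauss" else "gamma"
    got <- moverstayer:::marginal_lik_onelevel(
      matrix(log(P), 1), matrix(cs, 1), matrix(om, 1), gam, fam)
    want <- quad_marginal_onelevel(P, cs, om, gam, fam)
    expect_equal(got, want, tolerance = 1e-7)
  }
})

test_that("marginal stayer probability links contain logit and cloglog", {
  expect_equal(stayer_prob_gamma(0, 1), 0.5)   # logistic at gamma = 1
  expect_equal(stayer_prob_gamma(0.7, 1), plogis(0.7))
  expect_equal(stayer_prob_gamma(0, 1e-8), 1 - exp(-1), tolerance = 1e-6)
  # quadrature oracle: E_U[1 - exp(-U e^lp)]
  want <- quad_frailty_expect(function(u) 1 - exp(-u * exp(0.4)), 3.9,
                              "gamma")
  expect_equal(stayer_prob_gamma(0.4, 3.9), want, tolerance = 1e-9)
  # strictly increasing, in (0, 1)
  lp <- seq(-6, 6, by = 0.25)
  pg <- stayer_prob_gamma(lp, 3.9)
  expect_true(all(diff(pg) > 0) && all(pg > 0 & pg < 1))

  expect_equal(stayer_prob_invgauss(-30, 2), 0, tolerance = 1e-10)
  expect_equal(stayer_prob_invgauss(0.3, 1e-10), 1 - exp(-exp(0.3)),
               tolerance = 1e-6)
  want2 <- quad_frailty_expect(function(v) 1 - exp(-v * exp(-1)), 2,
                               "invgauss")
  expect_equal(stayer_prob_invgauss(-1, 2), want2, tolerance = 1e-8)
})

test_that("nested variants: TNB is the alpha -> -Inf limit and drops the frailty", {
  sim <- simulate_ms(sim_design(30, n_visits = 8), seed = 11)
  prm <- toy_params()
  # TNB contribution is the bare product of path probabilities
  L_tnb <- patient_likelihood(sim, prm, ms_model("tnb"))
  s <- area_summaries(sim, prm, ms_model("tnb"))
  expect_equal(unname(L_tnb), unname(exp(rowSums(s$log_path_prob))))
  # full model collapses onto TNB as all stayer intercepts -> -infinity
  prm_neg <- toy_params(alpha = c(-30, -30, -30))
  ll_full <- dataset_loglik(sim, prm_neg, ms_model("full"))
  ll_tnb <- dataset_loglik(sim, prm_neg, ms_model("tnb"))
  expect_lt(abs(ll_full - ll_tnb), 1e-8)
})

test_that("marginal likelihood is coherent over an enumerable outcome space", {
  caps <- joint_capacities(2, 2, 2)
  out1 <- enumerate_outcomes(2)
  prm <- toy_params(lambda0 = c(0.9, 0.5, 0.3), theta = c(1, 0.5, 0),
                    beta_diag = c(0.3, 0.1, 0.2))
  for (model in list(ms_model("full"), ms_model("tmsp"))) {
    p_tm <- prm
    if (model$variant == "tmsp") p_tm$theta[] <- 0
    total <- 0
    for (ih in seq_len(nrow(out1))) for (jf in seq_len(nrow(out1)))
      for (kl in seq_len(nrow(out1))) {
        counts <- cbind(c(0, out1$n1[ih]), c(0, out1$n1[jf]),
                        c(0, out1$n1[kl]))
        total <- total +
          patient_likelihood(toy_data(counts, caps = caps), p_tm, model)
      }
    expect_equal(unname(total), 1, tolerance = 1e-8)
  }
})

test_that("dataset log-likelihood is additive and handles edge patients", {
  sim <- simulate_ms(sim_design(20, n_visits = 6), seed = 5)
  prm <- toy_params()
  m <- ms_model("full")
  ll_all <- dataset_loglik(sim, prm, m)
  v <- sim$visits
  first <- visits_data(v[v$patient_id %in% unique(v$patient_id)[1:10], ])
  second <- visits_data(v[!v$patient_id %in% unique(v$patient_id)[1:10], ])
  expect_equal(dataset_loglik(first, prm, m) +
                 dataset_loglik(second, prm, m), ll_all)

  # full-model loglik against the per-patient quadrature oracle
  s <- area_summaries(sim, prm, m)
  want <- sum(log(vapply(seq_len(sim$n_patients), function(i)
    quad_marginal_onelevel(s$path_prob[i, ], s$ever_damaged[i, ],
                           s$omega[i, ], prm$gamma), numeric(1))))
  expect_equal(ll_all, want, tolerance = 1e-7)

  # a single-visit, zero-gap, undamaged patient is uninformative: L = 1
  L1 <- patient_likelihood(toy_data(cbind(0, 0, 0)), prm, m)
  expect_equal(unname(L1), 1)

  # single patient, TNB: log of the path-probability product
  one <- visits_data(v[v$patient_id == unique(v$patient_id)[1], ])
  expect_equal(dataset_loglik(one, prm, ms_model("tnb")),
               sum(area_summaries(one, prm,
                                  ms_model("tnb"))$log_path_prob))
})
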