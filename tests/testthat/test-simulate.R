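test_that("simulation is deterministic and respects path constraints", {
  des <- sim_design(60, n_visits = 9)
  d1 <- simulate_ms(des, seed = 21)
  d2 <- simulate_ms(des, seed = 21)
  expect_identical(d1$visits, d2$visits)
  d3 <- simulate_ms(des, seed = 22)
  expect_false(identical(d1$visits, d3$visits))

  v <- d1$visits
  for (k in c("hands", "feet", "large")) {
    col <- paste0("damaged_", k)
    expect_true(all(v[[col]] <= joint_capacities()[[k]]))
    expect_true(all(tapply(v[[col]], v$patient_id,
                           function(x) all(diff(x) >= 0))))
  }
  # simulated stayers never accumulate damage
  lat <- attr(d1, "latent")
  fin <- sapply(c("damaged_hands", "damaged_feet", "damaged_large"),
                function(col) tapply(v[[col]], v$patient_id, max))
  fin <- fin[order(unique(v$patient_id)), ]  # tapply sorts ids
  expect_true(all(fin[lat$mover == 0] == 0))
})

test_that("mover increments follow the truncated distribution they claim", {
  # beta = 0, theta = 0: increments are truncated Poisson; compare the
  # empirical mean of the exact sampler with the analytic truncated mean
  lam <- 0.5 * 0.61; Tk <- 20L; n <- 1e5
  set.seed(31)
  draws <- moverstayer:::rtrunc_nb(rep(lam, n), 0, rep(Tk, n))
  p <- truncated_nb_pmf(0:Tk, lam, 0, Tk)
  mu <- sum((0:Tk) * p)
  sdv <- sqrt(sum((0:Tk)^2 * p) - mu^2)
  expect_lt(abs(mean(draws) - mu), 3 * sdv / sqrt(n))
  # and with dispersion: distribution of draws matches the pmf (chi-square
  # on binned counts would be overkill; compare first two moments)
  set.seed(32)
  draws2 <- moverstayer:::rtrunc_nb(rep(1.3, n), 8, rep(10L, n))
  p2 <- truncated_nb_pmf(0:10, 1.3, 8, 10)
  mu2 <- sum((0:10) * p2)
  sd2 <- sqrt(sum((0:10)^2 * p2) - mu2^2)
  expect_lt(abs(mean(draws2) - mu2), 3 * sd2 / sqrt(n))
})

test_that("simulated stayer and damage-free fractions match analytic values", {
  # beta = 0 makes the all-zero mover path probability closed-form, so the
  # never-damaged fraction is 1 - LT(omega) (1 - p0^(visits-1))
  des <- sim_design(4000, n_visits = 10,
                    beta = matrix(0, 3, 3))
  dat <- simulate_ms(des, seed = 55)
  lat <- attr(dat, "latent")
  v <- dat$visits
  for (a in 1:3) {
    k <- c("hands", "feet", "large")[a]
    pi_star <- stayer_prob_gamma(des$alpha[[k]], des$gamma)
    f_stay <- mean(lat$mover[, a] == 0)
    se <- sqrt(pi_star * (1 - pi_star) / des$n_patients)
    expect_lt(abs(f_stay - pi_star), 3 * se)

    p0 <- truncated_nb_pmf(0, 0.5 * des$lambda0[[k]], des$theta[[k]],
                           joint_capacities()[[k]])
    f_free_true <- 1 - frailty_laplace(exp(des$alpha[[k]]), des$gamma) *
      (1 - p0^(des$n_visits - 1))
    fin <- tapply(v[[paste0("damaged_", k)]], v$patient_id, max)
    f_free <- mean(fin == 0)
    se2 <- sqrt(f_free_true * (1 - f_free_true) / des$n_patients)
    expect_lt(abs(f_free - f_free_true), 3 * se2)
  }
})

test_that("the simulator and the likelihood agree: truth beats perturbations", {
  des <- sim_design(400)
  dat <- simulate_ms(des, seed = 77)
  truth <- attr(dat, "truth")
  m <- ms_model("full")
  ll0 <- dataset_loglik(dat, truth, m)
  perturb <- function(tr, f) { p <- tr; f(p) }
  lls <- c(
    dataset_loglik(dat, perturb(truth, function(p) {
      p$lambda0 <- p$lambda0 * 1.2; p }), m),
    dataset_loglik(dat, perturb(truth, function(p) {
      p$theta <- p$theta * 0.8; p }), m),
    dataset_loglik(dat, perturb(truth, function(p) {
      p$gamma <- p$gamma * 1.2; p }), m),
    dataset_loglik(dat, perturb(truth, function(p) {
      p$beta <- lapply(p$beta, function(b) b + 0.02); p }), m),
    dataset_loglik(dat, perturb(truth, function(p) {
      p$lambda0 <- p$lambda0 * 1.2; p$theta <- p$theta * 1.2
      p$gamma <- p$gamma * 1.2
      p$alpha1 <- lapply(p$alpha1, function(a) a * 1.2)
      p$beta <- lapply(p$beta, function(b) b * 1.2); p }), m))
  expect_true(all(lls < ll0))
})

test_that("the study harness reports the recovery-table schema", {
  des <- sim_design(60, n_visits = 6)
  st <- simulation_study(des, n_reps = 3, seed = 5, se = FALSE)
  expect_s3_class(st, "ms_study")
  tab <- st$table
  expect_true(all(c("parameter", "true", "mean", "mean_se", "sd",
                    "mcse") %in% names(tab)))
  expect_true(all(paste0(rep(c("hands", "feet", "large"), each = 4), ":",
                         c("damaged_hands", "damaged_feet",
                           "damaged_large", "pi1")) %in% tab$parameter))
  expect_equal(tab["hands:damaged_hands", "true"], 0.1)
  expect_equal(tab["gamma", "true"], 3.9)
  expect_true(all(is.finite(tab$mean) & is.finite(tab$sd)))
  expect_equal(st$n_failed, 0L)
  # replicate r depends only on (seed, r): identical rerun
  st2 <- simulation_study(des, n_reps = 3, seed = 5, se = FALSE)
  expect_equal(st$table, st2$table)
})
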