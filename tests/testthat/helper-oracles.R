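# Independent numerical oracles and small fixture builders used across the
# suite. All quadrature here integrates the *conditional* likelihood
# against the frailty density directly (after a quantile or rational
# transform to tame the density's behaviour near 0), so it never shares
# code with the sign-expansion implementation it checks.

# unit-mean inverse-Gaussian density with variance psi (shape lambda = 1/psi)
dinvgauss_unit <- function(v, psi) {
  lam <- 1 / psi
  sqrt(lam / (2 * pi * v^3)) * exp(-lam * (v - 1)^2 / (2 * v))
}

# E[h(U)] for a unit-mean frailty, h vectorised
quad_frailty_expect <- function(h, variance, family,
                                rel.tol = 1e-11) {
  if (family == "gamma") {
    stats::integrate(function(p)
      h(stats::qgamma(p, shape = 1 / variance, scale = variance)),
      0, 1, rel.tol = rel.tol, abs.tol = 0, subdivisions = 500L)$value
  } else {
    stats::integrate(function(t) {
      v <- t / (1 - t)
      h(v) * dinvgauss_unit(v, variance) / (1 - t)^2
    }, 1e-12, 1 - 1e-12, rel.tol = rel.tol, abs.tol = 0,
    subdivisions = 500L)$value
  }
}

# one-level marginal patient likelihood by quadrature
quad_marginal_onelevel <- function(path_prob, cstar, omega, variance,
                                   family = "gamma") {
  quad_frailty_expect(function(u)
    conditional_patient_lik(path_prob, cstar, omega, pmax(u, 1e-300)),
    variance, family)
}

# two-level marginal by nested quadrature over (u, v)
quad_marginal_twolevel <- function(pre, q, case, omega1, omega2,
                                   gamma1, family1, gamma2, family2) {
  cond <- function(u, v)
    prod(vapply(1:3, function(k)
      twolevel_area_lik(pre[k], q[k], case[k], omega1[k], omega2[k],
                        u, v), numeric(1)))
  quad_frailty_expect(function(us)
    vapply(us, function(u)
      quad_frailty_expect(function(vs)
        vapply(vs, function(v) cond(max(u, 1e-300), max(v, 1e-300)),
               numeric(1)),
        gamma2, family2, rel.tol = 1e-9),
      numeric(1)),
    gamma1, family1, rel.tol = 1e-8)
}

# one-patient visit table: m visits at 6-month spacing starting at entry
# time 0, onset `onset_gap` years before entry, cumulative counts given as
# a matrix with one row per visit and columns hands/feet/large
toy_visits <- function(counts, onset_gap = 0, inter_visit = 0.5,
                       id = "P1") {
  counts <- matrix(counts, ncol = 3L)
  m <- nrow(counts)
  data.frame(patient_id = id, onset_time = -onset_gap,
             visit_time = (0:(m - 1L)) * inter_visit,
             damaged_hands = counts[, 1L], damaged_feet = counts[, 2L],
             damaged_large = counts[, 3L])
}

toy_data <- function(counts, onset_gap = 0, caps = joint_capacities(),
                     ...) {
  visits_data(toy_visits(counts, onset_gap = onset_gap, ...),
              capacities = caps)
}

# small generic parameter set for likelihood tests
toy_params <- function(gamma = 3.9, theta = c(8, 13, 8),
                       lambda0 = c(0.37, 0.61, 0.14),
                       alpha = c(0.26, -0.18, -0.33),
                       beta_diag = c(0.1, 0.04, 0),
                       preclinic = FALSE, alpha2 = NULL, gamma2 = NULL) {
  areas <- c("hands", "feet", "large")
  bet <- lapply(1:3, function(a) {
    b <- c(damaged_hands = 0, damaged_feet = 0, damaged_large = 0)
    b[a] <- beta_diag[a]
    b
  })
  names(bet) <- areas
  ms_params(
    lambda0 = lambda0, theta = theta, beta = bet,
    alpha1 = setNames(lapply(alpha, function(a) c("(Intercept)" = a)),
                      areas),
    gamma = gamma,
    lambda0_pre = if (preclinic) c(0.65, 0.54, 0.088),
    theta_pre = if (preclinic) c(4.7, 6.5, 3.88),
    alpha2 = if (!is.null(alpha2))
      setNames(lapply(alpha2, function(a) c("(Intercept)" = a)), areas),
    gamma2 = gamma2)
}

# enumerate all non-decreasing outcome paths for the clipped-capacity
# coherence checks: one observed interval, optional pre-clinic count
enumerate_outcomes <- function(cap, preclinic = FALSE) {
  if (preclinic) {
    g <- expand.grid(n0 = 0:cap, n1 = 0:cap)
    g[g$n1 >= g$n0, , drop = FALSE]
  } else data.frame(n0 = 0L, n1 = 0:cap)
}
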