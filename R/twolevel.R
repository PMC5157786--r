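## Two-level mover / clinic-induced-stayer / true-stayer likelihood.
##
## Each area's contribution conditional on the frailties (u, v) falls into
## one of three cases, with pi1 = 1 - exp(-u * omega1) (true stayer) and
## pi2 = 1 - exp(-v * omega2) (clinic-induced stayer, reachable only by
## movers):
##   never-damaged:            pi1 + (1-pi1) Pre0 [pi2 + (1-pi2) Q]
##   damaged only pre-clinic:  (1-pi1) Pre [pi2 + (1-pi2) Q]
##   damaged in clinic:        (1-pi1)(1-pi2) Pre Q
## where Pre is the pre-clinic entry-count probability and Q the in-clinic
## product of increment probabilities (all increments are 0 in the first
## two cases).

#' Conditional area likelihood for the two-level model
#'
#' One joint area's likelihood contribution conditional on both frailty
#' values, in the case determined by the observed path: `"never"` (no
#' damage ever), `"preclinic"` (damage present at clinic entry but none
#' accrued in clinic), or `"clinic"` (damage accrued in clinic).
#'
#' @param pre pre-clinic entry-count probability for the observed count.
#' @param q in-clinic path probability (product over observed intervals).
#' @param case one of `"never"`, `"preclinic"`, `"clinic"`.
#' @param omega1,omega2 stayer-component scales \eqn{e^{\alpha_1'z}},
#'   \eqn{e^{\alpha_2'z}}.
#' @param u,v positive frailty values.
#' @return likelihood value.
#' @export
twolevel_area_lik <- function(pre, q, case = c("never", "preclinic",
                                               "clinic"),
                              omega1, omega2, u, v) {
  case <- match.arg(case)
  pi1 <- 1 - exp(-u * omega1)
  pi2 <- 1 - exp(-v * omega2)
  switch(case,
    never     = pi1 + (1 - pi1) * pre * (pi2 + (1 - pi2) * q),
    preclinic = (1 - pi1) * pre * (pi2 + (1 - pi2) * q),
    clinic    = (1 - pi1) * (1 - pi2) * pre * q)
}

## Closed-form marginal likelihood by the double sign expansion: each
## area factor is written as a sum of at most three terms of the form
## w * exp(-u a omega1) * exp(-v b omega2) with a, b in {0, 1}:
##   never:     1 + e^{-u w1}(Pre0 - 1) - e^{-u w1}e^{-v w2} Pre0 (1 - Q)
##   preclinic: e^{-u w1} Pre - e^{-u w1}e^{-v w2} Pre (1 - Q)
##   clinic:    e^{-u w1}e^{-v w2} Pre Q
## Multiplying the three areas' sums and using the independence of U and V
## factorises every one of the <= 27 signed terms into
## w * LT_U(sum a_k omega1_k) * LT_V(sum b_k omega2_k).
marginal_lik_twolevel <- function(prep, lp, params, model) {
  npat <- prep$npat
  case <- matrix("clinic", npat, 3L)
  case[prep$nfinal == prep$n0 & prep$n0 > 0] <- "preclinic"
  case[prep$nfinal == 0] <- "never"
  marginal_lik_twolevel_core(
    exp(lp$logPre), exp(lp$logQ), case,
    omega_matrix(prep, params$alpha1), omega_matrix(prep, params$alpha2),
    params$gamma, model$frailty, params$gamma2, model$frailty2)
}

## core double expansion on raw per-area quantities (matrices with
## patients in rows, areas in columns)
marginal_lik_twolevel_core <- function(Pre, Q, case, omega1, omega2,
                                       gamma1, family1, gamma2, family2) {
  npat <- nrow(Pre)

  w <- a <- b <- array(0, dim = c(npat, 3L, 3L))  # patient, area, term
  for (k in 1:3) {
    nev <- case[, k] == "never"; prc <- case[, k] == "preclinic"
    cli <- case[, k] == "clinic"
    # term 1
    w[nev, k, 1] <- 1
    w[prc, k, 1] <- Pre[prc, k]
    a[prc, k, 1] <- 1
    w[cli, k, 1] <- Pre[cli, k] * Q[cli, k]
    a[cli, k, 1] <- 1; b[cli, k, 1] <- 1
    # term 2
    w[nev, k, 2] <- Pre[nev, k] - 1
    a[nev, k, 2] <- 1
    w[prc, k, 2] <- -Pre[prc, k] * (1 - Q[prc, k])
    a[prc, k, 2] <- 1; b[prc, k, 2] <- 1
    # term 3 (never-damaged case only)
    w[nev, k, 3] <- -Pre[nev, k] * (1 - Q[nev, k])
    a[nev, k, 3] <- 1; b[nev, k, 3] <- 1
  }

  L <- numeric(npat)
  for (i in 1:3) for (j in 1:3) for (m in 1:3) {
    wt <- w[, 1L, i] * w[, 2L, j] * w[, 3L, m]
    if (all(wt == 0)) next
    su <- a[, 1L, i] * omega1[, 1L] + a[, 2L, j] * omega1[, 2L] +
      a[, 3L, m] * omega1[, 3L]
    sv <- b[, 1L, i] * omega2[, 1L] + b[, 2L, j] * omega2[, 2L] +
      b[, 3L, m] * omega2[, 3L]
    L <- L + wt * frailty_laplace(su, gamma1, family1) *
      frailty_laplace(sv, gamma2, family2)
  }
  L
}
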