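## Per-patient, per-area path log-probabilities.
## Returns logQ (in-clinic product of truncated-NB increment probabilities)
## and logPre (pre-clinic entry-count probability; 0 when the pre-clinic
## period is not modelled), each an n_patients x 3 matrix.
path_logprobs <- function(prep, params) {
  npat <- prep$npat
  logQ <- logPre <- matrix(0, npat, 3L,
                           dimnames = list(NULL, AREA_NAMES))
  for (a in seq_along(AREA_NAMES)) {
    k <- AREA_NAMES[a]
    ar <- prep$areas[[k]]
    logQ[, a] <- cpp_area_path_loglik(
      ar$uid, ar$pid, npat, ar$d_u, ar$upper_u, ar$logdt_u, ar$Z_u,
      log(params$lambda0[[k]]), unname(params$beta[[k]]), params$theta[[k]])
    if (prep$has_preclinic) {
      lam_pre <- prep$onset_gap * params$lambda0_pre[[k]]
      logPre[, a] <- cpp_trunc_nb_logpmf(
        as.integer(prep$n0[, a]), lam_pre, params$theta_pre[[k]],
        rep(as.integer(prep$caps[[k]]), npat))
    }
  }
  list(logQ = logQ, logPre = logPre, logP = logQ + logPre)
}

## omega matrices exp(alpha' z*): n_patients x 3
omega_matrix <- function(prep, alpha) {
  m <- vapply(AREA_NAMES, function(k)
    exp(drop(prep$zstar %*% alpha[[k]])), numeric(prep$npat))
  matrix(m, nrow = prep$npat, dimnames = list(NULL, AREA_NAMES))
}

#' Per-area mover path probabilities and stayer-component summaries
#'
#' For every patient and joint area, the probability \eqn{P_{ik}} of the
#' observed damage path under the mover model (product of truncated
#' negative binomial increment probabilities over the observed intervals,
#' times the pre-clinic entry-count probability when modelled; an empty
#' interval product contributes 1), the stayer-component scale
#' \eqn{\omega_{ik} = \exp(\alpha_1^{k\prime} z^\star_i)}, and the
#' ever-damaged indicator \eqn{c^{*k}_i} (0 iff the final cumulative count
#' in the area is 0).
#'
#' @param data an `ms_data` object.
#' @param params an `ms_params` object.
#' @param model an `ms_model` spec.
#' @return list with matrices `path_prob`, `log_path_prob`, `omega`,
#'   `ever_damaged` (patients in rows, areas in columns).
#' @export
area_summaries <- function(data, params, model = ms_model()) {
  prep <- prepare_data(data, model)
  lp <- path_logprobs(prep, params)
  omega <- if (!is.null(params$alpha1)) omega_matrix(prep, params$alpha1)
  list(path_prob = exp(lp$logP), log_path_prob = lp$logP, omega = omega,
       ever_damaged = prep$cstar, patient_ids = prep$patient_ids)
}

#' Conditional patient likelihood given the frailty
#'
#' One patient's likelihood contribution conditional on the frailty value
#' \eqn{u}: the product over areas of
#' \eqn{[1 - e^{-u\omega_k}(1 - P_k)]} for never-damaged areas and
#' \eqn{e^{-u\omega_k} P_k} for areas with observed damage.
#'
#' @param path_prob length-3 vector of area path probabilities
#'   \eqn{P_{ik}}.
#' @param ever_damaged length-3 0/1 vector \eqn{c^{*k}}.
#' @param omega length-3 vector \eqn{\omega_{ik}}.
#' @param u positive frailty value (vectorised).
#' @return likelihood value(s).
#' @export
conditional_patient_lik <- function(path_prob, ever_damaged, omega, u) {
  stopifnot(length(path_prob) == 3L, length(ever_damaged) == 3L,
            length(omega) == 3L, all(u > 0))
  vapply(u, function(ui) {
    e <- exp(-ui * omega)
    prod(ifelse(ever_damaged == 1, e * path_prob,
                1 - e * (1 - path_prob)))
  }, numeric(1))
}

## Marginal patient likelihoods for the one-level model via the sign
## expansion over the subset lattice of never-damaged areas:
##   L_i = [prod_{k damaged} P_ik] *
##         sum_{r subset of never-damaged} (-1)^|r| prod_{k in r}(1 - P_ik)
##           * E[exp(-U sum_k omega_k (c*_k + r_k))]
## The Laplace-transform factors lie in (0,1]; the alternating sum is
## accumulated in linear space (it is an expectation of a positive
## quantity, hence positive), and the damaged-area product stays in logs.
SUBSET_LATTICE <- lapply(seq_len(8L), function(t) {
  r <- c(t %% 2L, (t %/% 2L) %% 2L, (t %/% 4L) %% 2L)
  list(idx = which(r == 1L), sign = (-1)^sum(r))
})

marginal_lik_onelevel <- function(logP, cstar, omega, variance, family) {
  npat <- nrow(logP)
  P <- exp(logP)
  base_lp <- rowSums(logP * cstar)
  s0 <- rowSums(omega * cstar)
  lt <- if (family == "gamma")
    function(s) exp(-log1p(variance * s) / variance)
  else function(s) exp((1 - sqrt(1 + 2 * variance * s)) / variance)
  bracket <- numeric(npat)
  for (sub in SUBSET_LATTICE) {
    idx <- sub$idx
    s <- s0
    valid <- rep(1, npat)
    pr <- rep(sub$sign, npat)
    for (k in idx) {
      valid <- valid * (1 - cstar[, k])
      s <- s + omega[, k]
      pr <- pr * (1 - P[, k])
    }
    bracket <- bracket + valid * pr * lt(s)
  }
  exp(base_lp) * bracket
}

#' Marginal per-patient likelihood contributions
#'
#' Computes each patient's likelihood contribution with the frailty
#' integrated out analytically. For the `full` and `tmsp` variants this is
#' the sign expansion over never-damaged areas combined with the frailty's
#' closed-form Laplace transform (at most 8 signed terms); `tnb` has no
#' stayer component, so the contribution is the plain product of area path
#' probabilities; `twolevel` uses the double expansion over both
#' frailties.
#'
#' @inheritParams area_summaries
#' @return numeric vector of per-patient likelihoods, named by patient id.
#' @export
patient_likelihood <- function(data, params, model = ms_model()) {
  prep <- prepare_data(data, model)
  L <- patient_likelihood_prepared(prep, params, model)
  stats::setNames(L, prep$patient_ids)
}

patient_likelihood_prepared <- function(prep, params, model) {
  lp <- path_logprobs(prep, params)
  switch(model$variant,
    tnb = exp(rowSums(lp$logP)),
    full = ,
    tmsp = marginal_lik_onelevel(lp$logP, prep$cstar,
                                 omega_matrix(prep, params$alpha1),
                                 params$gamma, model$frailty),
    twolevel = marginal_lik_twolevel(prep, lp, params, model))
}

#' Dataset log-likelihood
#'
#' Sum of the log marginal likelihood contributions over patients.
#' Contributions that underflow to zero are floored at a large negative
#' sentinel (with a warning) so optimisers receive a finite value.
#'
#' @inheritParams area_summaries
#' @return the log-likelihood (scalar).
#' @export
dataset_loglik <- function(data, params, model = ms_model()) {
  prep <- prepare_data(data, model)
  dataset_loglik_prepared(prep, params, model)
}

dataset_loglik_prepared <- function(prep, params, model) {
  L <- patient_likelihood_prepared(prep, params, model)
  bad <- !is.finite(L) | L <= 0
  if (any(bad)) {
    warning(sum(bad), " patient likelihood contribution(s) underflowed; ",
            "floored at exp(-700)", call. = FALSE)
    L[bad] <- exp(-700)
  }
  sum(log(L))
}
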