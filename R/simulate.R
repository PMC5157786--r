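#' Simulation design for the parameter-recovery study
#'
#' Describes the generating conditions of the full mover-stayer model:
#' every patient has `n_visits` equally spaced clinic visits, enters the
#' clinic at arthritis onset with no damaged joints (so the pre-clinic
#' model does not apply), a unit-mean gamma frailty with variance `gamma`,
#' per-area Bernoulli mover indicators, and truncated negative binomial
#' increments whose intensities carry the three attained damage counts as
#' dynamic covariates. The defaults are the study conditions used
#' throughout: 18 visits at 6-month spacing, baseline intensities
#' 0.37/0.61/0.14 per year, dispersions 8/13/8, frailty variance 3.9,
#' marginal stayer proportions 0.37/0.31/0.29, and cross-process
#' coefficients with hand damage driving all three areas
#' (hands 0.10 on hands; 0.08 on feet; 0.03 on large), foot damage 0.04 on
#' feet and large-joint damage 0.10 on feet, all others zero.
#'
#' @param n_patients number of patients per dataset.
#' @param n_visits number of clinic visits (>= 2).
#' @param inter_visit inter-visit spacing in years.
#' @param lambda0 per-area baseline intensities per year (hands, feet,
#'   large).
#' @param theta per-area dispersions.
#' @param beta 3x3 matrix of dynamic-covariate coefficients: rows = area
#'   modelled, columns = damage count entering the intensity
#'   (hands, feet, large).
#' @param stayer_prob per-area marginal stayer proportions; converted to
#'   the stayer intercepts via the inverse of the marginal gamma-frailty
#'   link at variance `gamma`.
#' @param gamma frailty variance.
#' @param capacities area capacities ([joint_capacities()]).
#' @param active simulate independent active-joint count columns (Poisson
#'   noise covariates, excluded from the generating intensities)?
#' @return an object of class `ms_design`.
#' @export
sim_design <- function(n_patients, n_visits = 18L, inter_visit = 0.5,
                       lambda0 = c(hands = 0.37, feet = 0.61, large = 0.14),
                       theta = c(hands = 8, feet = 13, large = 8),
                       beta = rbind(hands = c(0.10, 0, 0),
                                    feet  = c(0.08, 0.04, 0.10),
                                    large = c(0.03, 0, 0)),
                       stayer_prob = c(hands = 0.37, feet = 0.31,
                                       large = 0.29),
                       gamma = 3.9,
                       capacities = joint_capacities(),
                       active = FALSE) {
  stopifnot(n_visits >= 2L, inter_visit > 0, all(lambda0 > 0),
            all(theta >= 0), gamma > 0,
            all(stayer_prob > 0 & stayer_prob < 1))
  beta <- as.matrix(beta)
  dimnames(beta) <- list(AREA_NAMES, DAMAGE_COLS)
  alpha <- stayer_linpred_gamma(stayer_prob, gamma)
  structure(list(n_patients = as.integer(n_patients),
                 n_visits = as.integer(n_visits),
                 inter_visit = inter_visit,
                 lambda0 = stats::setNames(lambda0, AREA_NAMES),
                 theta = stats::setNames(theta, AREA_NAMES),
                 beta = beta,
                 stayer_prob = stats::setNames(stayer_prob, AREA_NAMES),
                 alpha = stats::setNames(alpha, AREA_NAMES),
                 gamma = gamma, capacities = capacities, active = active),
            class = "ms_design")
}

#' Generating parameters of a simulation design
#'
#' @param design an `ms_design`.
#' @return the corresponding `ms_params` truth record.
#' @export
sim_truth <- function(design) {
  ms_params(
    lambda0 = design$lambda0, theta = design$theta,
    beta = stats::setNames(
      lapply(AREA_NAMES, function(k)
        stats::setNames(design$beta[k, ], DAMAGE_COLS)), AREA_NAMES),
    alpha1 = stats::setNames(
      lapply(AREA_NAMES, function(k)
        c("(Intercept)" = unname(design$alpha[[k]]))), AREA_NAMES),
    gamma = design$gamma)
}

## draw truncated-NB increments for a vector of means with common
## dispersion and per-element truncation bounds, by inverting the exact
## categorical distribution over 0..upper
rtrunc_nb <- function(lam, theta, upper) {
  n <- length(lam)
  if (n == 0L) return(integer(0))
  maxu <- max(upper)
  r <- 0:maxu
  f <- vapply(r, function(rr) {
    if (theta == 0) stats::dpois(rr, lam)
    else stats::dnbinom(rr, size = 1 / theta, mu = lam)
  }, numeric(n))
  f <- matrix(f, nrow = n)
  f[outer(upper, r, `<`)] <- 0
  cum <- t(apply(f, 1L, cumsum))
  tot <- cum[, maxu + 1L]
  u <- stats::runif(n) * tot
  as.integer(rowSums(cum < u))
}

#' Simulate a dataset from the full mover-stayer model
#'
#' Draws, per patient, a gamma frailty `u`; per area a mover indicator
#' with success probability \eqn{\exp(-u e^{\alpha_k})}; and, for movers,
#' truncated negative binomial increments with mean
#' \eqn{\Delta t\,\lambda_0^k \exp(\beta_h n^h + \beta_f n^f + \beta_l
#' n^l)} evaluated at the interval's attained counts and truncated to the
#' remaining capacity, sampled by exact categorical draws. Stayers keep
#' all-zero paths; all areas' counts are advanced jointly at each
#' interval. Patients enter at onset with zero damage.
#'
#' @param design an `ms_design`.
#' @param seed integer seed; the dataset is a deterministic function of
#'   `(design, seed)`.
#' @return an `ms_data` object; `attr(, "truth")` holds the generating
#'   `ms_params`, `attr(, "latent")` the frailties and mover indicators.
#' @export
simulate_ms <- function(design, seed = 1L) {
  stopifnot(inherits(design, "ms_design"))
  set.seed(seed)
  n <- design$n_patients
  nv <- design$n_visits
  caps <- design$capacities
  u <- stats::rgamma(n, shape = 1 / design$gamma, scale = design$gamma)
  mover <- matrix(vapply(AREA_NAMES, function(k)
    stats::rbinom(n, 1L, exp(-u * exp(design$alpha[[k]]))), integer(n)),
    nrow = n, dimnames = list(NULL, AREA_NAMES))

  N <- matrix(0L, n, 3L, dimnames = list(NULL, AREA_NAMES))
  paths <- array(0L, dim = c(n, nv, 3L))
  for (j in seq_len(nv - 1L)) {
    D <- matrix(0L, n, 3L)
    for (a in 1:3) {
      k <- AREA_NAMES[a]
      idx <- which(mover[, a] == 1L & N[, a] < caps[[k]])
      if (length(idx)) {
        lam <- design$inter_visit * design$lambda0[[k]] *
          exp(drop(N[idx, , drop = FALSE] %*% design$beta[k, ]))
        D[idx, a] <- rtrunc_nb(lam, design$theta[[k]],
                               caps[[k]] - N[idx, a])
      }
    }
    N <- N + D
    paths[, j + 1L, ] <- N
  }

  visit_time <- rep((0:(nv - 1L)) * design$inter_visit, times = n)
  df <- data.frame(
    patient_id = rep(sprintf("P%04d", seq_len(n)), each = nv),
    onset_time = 0, visit_time = visit_time,
    damaged_hands = as.vector(t(paths[, , 1L])),
    damaged_feet = as.vector(t(paths[, , 2L])),
    damaged_large = as.vector(t(paths[, , 3L])))
  if (isTRUE(design$active))
    for (k in AREA_NAMES)
      df[[paste0("active_", k)]] <- stats::rpois(nrow(df), 2)
  out <- visits_data(df, capacities = caps)
  attr(out, "truth") <- sim_truth(design)
  attr(out, "latent") <- list(u = u, mover = mover)
  out
}

## true values in the row order of the study table
study_true_values <- function(design) {
  truth <- sim_truth(design)
  vals <- c()
  for (k in AREA_NAMES) {
    vals <- c(vals, stats::setNames(design$beta[k, ],
                                    paste0(k, ":", DAMAGE_COLS)))
    vals <- c(vals, stats::setNames(design$stayer_prob[[k]],
                                    paste0(k, ":pi1")))
  }
  for (k in AREA_NAMES)
    vals <- c(vals,
              stats::setNames(design$lambda0[[k]], paste0(k, ":lambda0")),
              stats::setNames(design$theta[[k]], paste0(k, ":theta")))
  c(vals, gamma = design$gamma)
}

#' Parameter-recovery simulation study
#'
#' Repeatedly simulates datasets from a design, refits the model to each,
#' and tabulates per parameter the replicate-mean estimate, mean estimated
#' standard error, standard deviation of the estimates, and the
#' Monte-Carlo standard error of the mean. Replicate `r` uses the derived
#' seed `(seed + 104729 r) mod (2^31 - 1)`, so each replicate depends only
#' on the master seed and its index. Failed or non-converged fits are
#' excluded and counted; more than 20\% failures aborts the study.
#'
#' @param design an `ms_design`.
#' @param n_reps number of replicates (>= 2).
#' @param model model spec to fit (default the full model).
#' @param seed master seed.
#' @param se compute per-replicate standard errors (needed for the mean-SE
#'   column and coverage work; disable to speed up pure bias studies)?
#' @param keep_fits return the per-replicate estimate matrix?
#' @return an object of class `ms_study`: `table` (one row per parameter:
#'   `true`, `mean`, `mean_se`, `sd`, `mcse`), `n_reps`, `n_failed`, and
#'   optionally `estimates`/`ses` matrices.
#' @export
simulation_study <- function(design, n_reps, model = ms_model("full"),
                             seed = 1L, se = TRUE, keep_fits = FALSE) {
  stopifnot(n_reps >= 2L)
  rows <- names(study_true_values(design))
  est <- ses <- matrix(NA_real_, n_reps, length(rows),
                       dimnames = list(NULL, rows))
  failed <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    seed_r <- as.integer((seed + 104729 * r) %% 2147483647)
    dat <- simulate_ms(design, seed = seed_r)
    fit <- tryCatch(fit_ms(dat, model, control = list(se = se)),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$diagnostics$converged) {
      failed[r] <- TRUE
      next
    }
    grab <- function(col, wname, scale = 1) {
      if (wname %in% rownames(fit$estimates))
        fit$estimates[wname, col] * scale else NA_real_
    }
    for (k in AREA_NAMES) {
      for (b in DAMAGE_COLS) {
        est[r, paste0(k, ":", b)] <- grab("estimate", paste0(k, ":b_", b))
        ses[r, paste0(k, ":", b)] <- grab("se_working", paste0(k, ":b_", b))
      }
      for (nat in c("lambda0", "theta")) {
        w <- paste0(k, ":log_", nat)
        est[r, paste0(k, ":", nat)] <- grab("estimate", w)
        ses[r, paste0(k, ":", nat)] <-
          grab("se_working", w, grab("estimate", w))
      }
    }
    if (!is.null(fit$derived)) {
      est[r, paste0(AREA_NAMES, ":pi1")] <- fit$derived$pi1
      ses[r, paste0(AREA_NAMES, ":pi1")] <- fit$derived$se
    }
    est[r, "gamma"] <- grab("estimate", "log_gamma")
    ses[r, "gamma"] <- grab("se_working", "log_gamma",
                            grab("estimate", "log_gamma"))
  }
  n_failed <- sum(failed)
  if (n_failed > 0.2 * n_reps)
    stop(sprintf("simulation study: %d/%d fits failed", n_failed, n_reps),
         call. = FALSE)
  ok <- !failed
  tab <- data.frame(
    parameter = rows,
    true = unname(study_true_values(design)),
    mean = colMeans(est[ok, , drop = FALSE], na.rm = TRUE),
    mean_se = colMeans(ses[ok, , drop = FALSE], na.rm = TRUE),
    sd = apply(est[ok, , drop = FALSE], 2L, stats::sd, na.rm = TRUE),
    row.names = rows)
  tab$mcse <- tab$sd / sqrt(sum(ok))
  out <- list(table = tab, n_reps = n_reps, n_failed = n_failed,
              design = design, seed = seed)
  if (keep_fits) { out$estimates <- est; out$ses <- ses }
  structure(out, class = "ms_study")
}

#' @export
print.ms_study <- function(x, ...) {
  cat(sprintf(
    "Parameter-recovery study: %d patients x %d replicates (%d failed)\n",
    x$design$n_patients, x$n_reps, x$n_failed))
  tab <- x$table
  tab[-1L] <- lapply(tab[-1L], signif, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
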