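#' Specify a trivariate mover-stayer model variant
#'
#' Selects one of the model variants and the frailty distribution(s):
#' \describe{
#'   \item{`full`}{mover-stayer truncated negative binomial margins with a
#'     shared patient-level frailty in the stayer components.}
#'   \item{`tnb`}{truncated negative binomial margins only (stayer
#'     probabilities fixed at zero, no frailty).}
#'   \item{`tmsp`}{mover-stayer truncated Poisson margins: all in-clinic
#'     and pre-clinic dispersions fixed at zero, frailty retained.}
#'   \item{`twolevel`}{two-level margins distinguishing true stayers
#'     (immune before and after clinic entry) from clinic-induced stayers
#'     (movers who become immune at clinic entry), with two independent
#'     unit-mean frailties.}
#' }
#'
#' @param variant model variant, see above.
#' @param frailty distribution of the true-stayer frailty `U`: `"gamma"`
#'   (variance `gamma`) or `"invgauss"` (variance `psi`).
#' @param frailty2 distribution of the clinic-induced-stayer frailty `V`
#'   (two-level variant only). Inverse Gaussian is the default: its density
#'   vanishes at 0, which avoids the identifiability problem of a
#'   heavy-at-zero gamma frailty mimicking a near-zero stayer probability.
#' @param covariates character vector of extra visit-level covariate
#'   columns (e.g. active-joint counts) entering every area's progression
#'   intensity; the three attained damage counts are always included.
#' @param stayer_covariates character vector of time-invariant covariate
#'   columns for the stayer linear predictors (intercept-only by default).
#' @param preclinic logical: model the damage count accumulated between
#'   arthritis onset and clinic entry? `NA` (default) resolves to whether
#'   the data show any pre-clinic exposure (positive onset-to-entry time
#'   or entry damage).
#' @return an object of class `ms_model`.
#' @export
ms_model <- function(variant = c("full", "tnb", "tmsp", "twolevel"),
                     frailty = c("gamma", "invgauss"),
                     frailty2 = c("invgauss", "gamma"),
                     covariates = character(),
                     stayer_covariates = character(),
                     preclinic = NA) {
  structure(list(variant = match.arg(variant),
                 frailty = match.arg(frailty),
                 frailty2 = match.arg(frailty2),
                 covariates = as.character(covariates),
                 stayer_covariates = as.character(stayer_covariates),
                 preclinic = preclinic),
            class = "ms_model")
}

#' @export
print.ms_model <- function(x, ...) {
  cat("Trivariate mover-stayer model spec\n")
  cat("  variant:", x$variant, "\n")
  if (x$variant != "tnb") cat("  frailty U:", x$frailty, "\n")
  if (x$variant == "twolevel") cat("  frailty V:", x$frailty2, "\n")
  if (length(x$covariates))
    cat("  extra covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

## names of the mover regression coefficients, in design-matrix order:
## extra covariates first, then the three dynamic damage counts
beta_names <- function(model) c(model$covariates, DAMAGE_COLS)

alpha_names <- function(model) c("(Intercept)", model$stayer_covariates)

#' Construct a full parameter set
#'
#' Bundles per-area progression parameters and stayer-component parameters
#' into the list structure the likelihood and simulator consume. Entries
#' irrelevant to a variant (e.g. `alpha1` under `tnb`) may be left `NULL`.
#'
#' @param lambda0 named vector of positive baseline intensities per year
#'   (hands, feet, large).
#' @param theta named vector of non-negative dispersions.
#' @param beta list of per-area coefficient vectors, each in the order
#'   extra covariates then `damaged_hands`, `damaged_feet`,
#'   `damaged_large`.
#' @param alpha1 list of per-area true-stayer linear-predictor coefficient
#'   vectors (first entry the intercept).
#' @param gamma variance of the unit-mean frailty `U` (gamma or inverse
#'   Gaussian, per the model spec).
#' @param lambda0_pre,theta_pre pre-clinic baseline intensities and
#'   dispersions (only when the pre-clinic period is modelled).
#' @param alpha2 per-area clinic-induced-stayer coefficients (two-level).
#' @param gamma2 variance of the second frailty `V` (two-level).
#' @return an object of class `ms_params`.
#' @export
ms_params <- function(lambda0, theta, beta, alpha1 = NULL, gamma = NULL,
                      lambda0_pre = NULL, theta_pre = NULL,
                      alpha2 = NULL, gamma2 = NULL) {
  as_area_vec <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.null(names(x))) names(x) <- AREA_NAMES
    x[AREA_NAMES]
  }
  p <- structure(list(
    lambda0 = as_area_vec(lambda0), theta = as_area_vec(theta),
    beta = if (!is.null(beta)) beta[AREA_NAMES],
    alpha1 = if (!is.null(alpha1)) alpha1[AREA_NAMES],
    gamma = gamma,
    lambda0_pre = as_area_vec(lambda0_pre),
    theta_pre = as_area_vec(theta_pre),
    alpha2 = if (!is.null(alpha2)) alpha2[AREA_NAMES],
    gamma2 = gamma2), class = "ms_params")
  stopifnot(all(p$lambda0 > 0), all(p$theta >= 0))
  if (!is.null(p$gamma)) stopifnot(p$gamma > 0)
  if (!is.null(p$gamma2)) stopifnot(p$gamma2 > 0)
  p
}

## ---- working-scale packing ------------------------------------------------
## Layout of the unconstrained working parameter vector for a given model.
## Positive parameters (lambda0, theta, gamma, ...) are log-transformed;
## regression coefficients enter untransformed. TM-SP fixes all dispersions
## at 0 (not packed); TNB drops the stayer component entirely.
param_layout <- function(model, has_preclinic) {
  free_theta <- model$variant != "tmsp"
  with_stayer <- model$variant != "tnb"
  nm <- character(0)
  for (k in AREA_NAMES) {
    nm <- c(nm, paste0(k, ":log_lambda0"))
    if (free_theta) nm <- c(nm, paste0(k, ":log_theta"))
    nm <- c(nm, paste0(k, ":b_", beta_names(model)))
    if (with_stayer) nm <- c(nm, paste0(k, ":a1_", alpha_names(model)))
    if (model$variant == "twolevel")
      nm <- c(nm, paste0(k, ":a2_", alpha_names(model)))
    if (has_preclinic) {
      nm <- c(nm, paste0(k, ":log_lambda0_pre"))
      if (free_theta) nm <- c(nm, paste0(k, ":log_theta_pre"))
    }
  }
  if (with_stayer) nm <- c(nm, "log_gamma")
  if (model$variant == "twolevel") nm <- c(nm, "log_gamma2")
  list(names = nm, free_theta = free_theta, with_stayer = with_stayer,
       has_preclinic = has_preclinic, model = model,
       p_beta = length(beta_names(model)), p_alpha = length(alpha_names(model)))
}

pack_params <- function(params, layout) {
  model <- layout$model
  w <- numeric(0)
  for (k in AREA_NAMES) {
    w <- c(w, log(params$lambda0[[k]]))
    if (layout$free_theta) w <- c(w, log(params$theta[[k]]))
    w <- c(w, unname(params$beta[[k]]))
    if (layout$with_stayer) w <- c(w, unname(params$alpha1[[k]]))
    if (model$variant == "twolevel") w <- c(w, unname(params$alpha2[[k]]))
    if (layout$has_preclinic) {
      w <- c(w, log(params$lambda0_pre[[k]]))
      if (layout$free_theta) w <- c(w, log(params$theta_pre[[k]]))
    }
  }
  if (layout$with_stayer) w <- c(w, log(params$gamma))
  if (model$variant == "twolevel") w <- c(w, log(params$gamma2))
  stats::setNames(w, layout$names)
}

unpack_params <- function(w, layout) {
  model <- layout$model
  i <- 0L
  take <- function(n) { out <- w[i + seq_len(n)]; i <<- i + n; out }
  lambda0 <- theta <- lambda0_pre <- theta_pre <- numeric(0)
  beta <- alpha1 <- alpha2 <- list()
  for (k in AREA_NAMES) {
    lambda0[[k]] <- exp(take(1L))
    theta[[k]] <- if (layout$free_theta) exp(take(1L)) else 0
    beta[[k]] <- stats::setNames(take(layout$p_beta), beta_names(model))
    if (layout$with_stayer)
      alpha1[[k]] <- stats::setNames(take(layout$p_alpha), alpha_names(model))
    if (model$variant == "twolevel")
      alpha2[[k]] <- stats::setNames(take(layout$p_alpha), alpha_names(model))
    if (layout$has_preclinic) {
      lambda0_pre[[k]] <- exp(take(1L))
      theta_pre[[k]] <- if (layout$free_theta) exp(take(1L)) else 0
    }
  }
  gamma <- if (layout$with_stayer) exp(take(1L)) else NULL
  gamma2 <- if (model$variant == "twolevel") exp(take(1L)) else NULL
  ms_params(lambda0 = lambda0, theta = theta, beta = beta,
            alpha1 = if (layout$with_stayer) alpha1 else NULL,
            gamma = gamma,
            lambda0_pre = if (layout$has_preclinic) lambda0_pre else NULL,
            theta_pre = if (layout$has_preclinic) theta_pre else NULL,
            alpha2 = if (model$variant == "twolevel") alpha2 else NULL,
            gamma2 = gamma2)
}
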