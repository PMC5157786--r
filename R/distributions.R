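#' Negative binomial probability mass function with mean/dispersion parameters
#'
#' Density of the negative binomial distribution parameterised by its mean
#' \eqn{\Lambda} and dispersion \eqn{\theta \ge 0}:
#' \deqn{f_{nb}(r \mid \Lambda, \theta) =
#'   \frac{\Gamma(r + 1/\theta)}{\Gamma(1/\theta)\, r!}
#'   \left(\frac{\theta\Lambda}{1+\theta\Lambda}\right)^r
#'   (1+\theta\Lambda)^{-1/\theta},}
#' so that the variance is \eqn{\Lambda(1 + \theta\Lambda)}. At
#' \eqn{\theta = 0} the Poisson pmf with mean \eqn{\Lambda} is returned
#' (the continuous limit), as an exact branch rather than a small-theta
#' approximation.
#'
#' @param x vector of non-negative integer counts.
#' @param mean positive mean \eqn{\Lambda} (recycled against `x`).
#' @param dispersion non-negative dispersion \eqn{\theta} (scalar).
#' @param log logical; return log probabilities?
#' @return numeric vector of (log) probabilities.
#' @examples
#' nb_pmf(0, mean = 2, dispersion = 0.5)  # (1 + 1)^-2 = 0.25
#' nb_pmf(3, mean = 1.7, dispersion = 0)  # dpois(3, 1.7)
#' @export
nb_pmf <- function(x, mean, dispersion, log = FALSE) {
  if (any(x < 0) || any(x != floor(x)))
    stop("'x' must contain non-negative integers", call. = FALSE)
  if (any(mean <= 0)) stop("'mean' must be positive", call. = FALSE)
  if (length(dispersion) != 1L || is.na(dispersion) || dispersion < 0)
    stop("'dispersion' must be a single non-negative number", call. = FALSE)
  lp <- if (dispersion == 0) {
    stats::dpois(x, lambda = mean, log = TRUE)
  } else {
    stats::dnbinom(x, size = 1 / dispersion, mu = mean, log = TRUE)
  }
  if (log) lp else exp(lp)
}

#' Right-truncated negative binomial pmf
#'
#' The negative binomial pmf renormalised over the support
#' \eqn{\{0, \dots, upper\}}, where `upper` is the remaining undamaged-joint
#' capacity (area capacity minus the attained damage count for in-clinic
#' increments; the full capacity for the pre-clinic-entry count). The
#' denominator is the finite sum \eqn{\sum_{r=0}^{upper} f_{nb}(r)},
#' accumulated by log-sum-exp.
#'
#' @param x vector of counts in `0:upper`.
#' @param mean positive mean of the untruncated distribution.
#' @param dispersion non-negative dispersion (scalar); 0 gives the
#'   truncated Poisson.
#' @param upper non-negative integer truncation bound (scalar).
#' @param log logical; return log probabilities?
#' @return numeric vector of (log) probabilities; `upper = 0` is the point
#'   mass at 0 (a saturated joint area can accrue no further damage).
#' @examples
#' sum(truncated_nb_pmf(0:5, mean = 1, dispersion = 0.5, upper = 5))  # 1
#' @export
truncated_nb_pmf <- function(x, mean, dispersion, upper, log = FALSE) {
  if (length(upper) != 1L || upper < 0 || upper != floor(upper))
    stop("'upper' must be a single non-negative integer", call. = FALSE)
  if (any(x > upper))
    stop("'x' exceeds the truncation bound 'upper'", call. = FALSE)
  if (length(mean) != 1L || mean <= 0)
    stop("'mean' must be a single positive number", call. = FALSE)
  lp_all <- nb_pmf(0:upper, mean, dispersion, log = TRUE)
  lden <- logsumexp(lp_all)
  lp <- lp_all[x + 1L] - lden
  if (log) lp else exp(lp)
}

## log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Interval intensity with dynamic covariates
#'
#' Expected number of new damaged joints for one inter-visit interval of a
#' mover, \eqn{\Lambda = \Delta t \, \lambda_0 \exp(\beta' z)}, where
#' \eqn{z} stacks any configured visit-level covariates and the attained
#' damage counts in the three joint areas, all evaluated at the interval's
#' left endpoint (values at visit \eqn{j} predict the increment to visit
#' \eqn{j+1}).
#'
#' @param interval_length positive interval length in years.
#' @param dynamic_counts numeric vector of length 3 (attained damage counts
#'   in hands, feet, large joints at the interval start), or a 3-column
#'   matrix with one row per interval.
#' @param area_params list with entries `lambda0` (positive baseline
#'   intensity per year) and `beta` (coefficient vector: any extra
#'   covariates first, then the three damage counts in hands/feet/large
#'   order).
#' @param covariates optional named numeric vector (or matrix) of extra
#'   covariate values at the interval start; names must match the leading
#'   `beta` entries.
#' @return positive intensity (vector if matrix input).
#' @examples
#' p <- list(lambda0 = 0.15, beta = c(hands = 0, feet = 0, large = 0))
#' interval_intensity(0.5, c(0, 0, 0), p)  # 0.075
#' @export
interval_intensity <- function(interval_length, dynamic_counts, area_params,
                               covariates = NULL) {
  if (any(interval_length <= 0))
    stop("'interval_length' must be positive", call. = FALSE)
  z <- if (is.matrix(dynamic_counts)) dynamic_counts else
    matrix(dynamic_counts, nrow = 1L)
  if (ncol(z) != 3L)
    stop("'dynamic_counts' must have three columns (hands, feet, large)",
         call. = FALSE)
  beta <- area_params$beta
  p_extra <- length(beta) - 3L
  if (p_extra < 0L) stop("'beta' must have at least 3 entries", call. = FALSE)
  eta <- drop(z %*% beta[p_extra + (1:3)])
  if (p_extra > 0L) {
    if (is.null(covariates))
      stop("model configures extra covariates but none supplied",
           call. = FALSE)
    zc <- if (is.matrix(covariates)) covariates else
      matrix(covariates, nrow = nrow(z), ncol = p_extra, byrow = TRUE,
             dimnames = list(NULL, names(covariates)))
    nm <- names(beta)[seq_len(p_extra)]
    if (!all(nm %in% colnames(zc)))
      stop("missing configured covariate(s): ",
           paste(setdiff(nm, colnames(zc)), collapse = ", "), call. = FALSE)
    eta <- eta + drop(zc[, nm, drop = FALSE] %*% beta[seq_len(p_extra)])
  }
  interval_length * area_params$lambda0 * exp(eta)
}

#' Pre-clinic-entry damage count distribution
#'
#' Distribution of the damage count attained between arthritis onset and
#' clinic entry, given no damage at onset: a truncated negative binomial
#' with mean \eqn{(t_{entry} - t_{onset})\,\lambda_0^{0}}, dispersion
#' \eqn{\theta^{0}} and truncation at the full area capacity. A zero
#' onset-to-entry time gives the degenerate point mass at 0.
#'
#' @param x vector of counts in `0:capacity`.
#' @param onset_to_entry non-negative time from arthritis onset to clinic
#'   entry, in years.
#' @param lambda0_pre positive pre-clinic baseline intensity per year.
#' @param theta_pre non-negative pre-clinic dispersion.
#' @param capacity area joint capacity (28 hands, 20 feet, 16 large).
#' @param log logical; return log probabilities?
#' @return numeric vector of (log) probabilities.
#' @export
preclinic_prob <- function(x, onset_to_entry, lambda0_pre, theta_pre,
                           capacity, log = FALSE) {
  if (onset_to_entry < 0)
    stop("'onset_to_entry' must be non-negative", call. = FALSE)
  if (any(x > capacity))
    stop("'x' exceeds the area capacity", call. = FALSE)
  if (onset_to_entry == 0) {
    lp <- ifelse(x == 0, 0, -Inf)
    return(if (log) lp else exp(lp))
  }
  truncated_nb_pmf(x, mean = onset_to_entry * lambda0_pre,
                   dispersion = theta_pre, upper = capacity, log = log)
}

#' Laplace transform of a unit-mean frailty distribution
#'
#' \eqn{E[\exp(-sU)]} for a positive unit-mean random effect:
#' gamma with variance \eqn{\gamma} gives \eqn{(1+\gamma s)^{-1/\gamma}};
#' inverse Gaussian with variance \eqn{\psi} gives
#' \eqn{\exp\{(1/\psi)(1 - \sqrt{1 + 2\psi s})\}}. These closed forms are
#' what make the marginal likelihood analytic after the sign expansion.
#'
#' @param s non-negative argument (vectorised).
#' @param variance positive frailty variance.
#' @param family `"gamma"` or `"invgauss"`.
#' @return \eqn{E[e^{-sU}]}, in (0, 1].
#' @export
frailty_laplace <- function(s, variance, family = c("gamma", "invgauss")) {
  family <- match.arg(family)
  if (variance <= 0) stop("'variance' must be positive", call. = FALSE)
  switch(family,
    gamma    = exp(-log1p(variance * s) / variance),
    invgauss = exp((1 - sqrt(1 + 2 * variance * s)) / variance)
  )
}

#' Marginal stayer probability under a gamma frailty
#'
#' The population-level stayer probability obtained by integrating the
#' conditional complementary log-log component
#' \eqn{\pi(u) = 1 - \exp(-u e^{lp})} over a unit-mean gamma frailty with
#' variance \eqn{\gamma}:
#' \deqn{\pi^{*} = 1 - (1 + \gamma e^{lp})^{-1/\gamma}.}
#' This link family contains the logistic link at \eqn{\gamma = 1} and the
#' complementary log-log link in the limit \eqn{\gamma \to 0}.
#'
#' @param lin_pred linear predictor \eqn{\alpha' z^{\star}} (vectorised).
#' @param gamma positive frailty variance.
#' @return probability in (0, 1).
#' @examples
#' stayer_prob_gamma(0, 1)  # 0.5, the logistic link
#' @export
stayer_prob_gamma <- function(lin_pred, gamma) {
  if (gamma <= 0) stop("'gamma' must be positive", call. = FALSE)
  1 - frailty_laplace(exp(lin_pred), gamma, "gamma")
}

#' Marginal stayer probability under an inverse-Gaussian frailty
#'
#' As [stayer_prob_gamma()] but integrating over a unit-mean inverse
#' Gaussian frailty with variance \eqn{\psi}:
#' \deqn{\pi^{*} = 1 - \exp\{(1/\psi)(1 - \sqrt{1 + 2\psi e^{lp}})\}.}
#' As \eqn{\psi \to 0} this approaches the complementary log-log inverse
#' \eqn{1 - \exp(-e^{lp})}.
#'
#' @param lin_pred linear predictor (vectorised).
#' @param psi positive frailty variance.
#' @return probability in (0, 1).
#' @export
stayer_prob_invgauss <- function(lin_pred, psi) {
  if (psi <= 0) stop("'psi' must be positive", call. = FALSE)
  1 - frailty_laplace(exp(lin_pred), psi, "invgauss")
}

## inverse of the marginal gamma-frailty stayer link: linear predictor
## giving stayer probability pi at frailty variance gamma
stayer_linpred_gamma <- function(pi, gamma) {
  log(expm1(-gamma * log1p(-pi)) / gamma)
}
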