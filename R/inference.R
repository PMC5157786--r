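#' Observed information matrix by central finite differences
#'
#' Negative Hessian of a log-likelihood function at a (working-scale)
#' point, by central second differences with per-coordinate relative step,
#' symmetrised. Inverting this at the maximum likelihood estimate gives
#' the asymptotic covariance used for Wald intervals.
#'
#' @param loglik_fn function of the working parameter vector returning the
#'   log-likelihood.
#' @param at evaluation point (numeric vector).
#' @param rel_step relative step size per coordinate (default `1e-4`;
#'   absolute step `rel_step * max(1, |at_i|)`).
#' @return symmetric matrix \eqn{-H}.
#' @export
observed_information <- function(loglik_fn, at, rel_step = 1e-4) {
  p <- length(at)
  h <- rel_step * pmax(1, abs(at))
  f0 <- loglik_fn(at)
  if (!is.finite(f0)) stop("log-likelihood not finite at 'at'", call. = FALSE)
  H <- matrix(NA_real_, p, p)
  shift <- function(i, s) { x <- at; x[i] <- x[i] + s; x }
  for (i in seq_len(p)) {
    fp <- loglik_fn(shift(i, h[i]))
    fm <- loglik_fn(shift(i, -h[i]))
    if (!is.finite(fp) || !is.finite(fm))
      stop("non-finite log-likelihood when perturbing coordinate ",
           if (!is.null(names(at))) names(at)[i] else i, call. = FALSE)
    H[i, i] <- (fp - 2 * f0 + fm) / h[i]^2
    for (j in seq_len(i - 1L)) {
      x <- at
      fpp <- { x <- at; x[i] <- x[i] + h[i]; x[j] <- x[j] + h[j]; loglik_fn(x) }
      fpm <- { x <- at; x[i] <- x[i] + h[i]; x[j] <- x[j] - h[j]; loglik_fn(x) }
      fmp <- { x <- at; x[i] <- x[i] - h[i]; x[j] <- x[j] + h[j]; loglik_fn(x) }
      fmm <- { x <- at; x[i] <- x[i] - h[i]; x[j] <- x[j] - h[j]; loglik_fn(x) }
      if (!all(is.finite(c(fpp, fpm, fmp, fmm))))
        stop("non-finite log-likelihood when perturbing coordinates ",
             i, ", ", j, call. = FALSE)
      H[i, j] <- H[j, i] <- (fpp - fpm - fmp + fmm) / (4 * h[i] * h[j])
    }
  }
  info <- -(H + t(H)) / 2
  dimnames(info) <- list(names(at), names(at))
  info
}

## invert an information matrix, falling back to the Moore-Penrose
## pseudo-inverse (with a warning) when ill-conditioned or singular
invert_information <- function(info) {
  ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
  cond_bad <- min(ev) <= 0 || max(ev) / min(ev) > 1e12
  if (cond_bad) {
    warning("observed information is singular or ill-conditioned ",
            "(condition number > 1e12); using pseudo-inverse",
            call. = FALSE)
    return(MASS::ginv(info))
  }
  solve(info)
}

#' Delta-method standard errors
#'
#' Standard error of a smooth transform \eqn{g} of the working parameters:
#' \eqn{\sqrt{\nabla g' \Sigma \nabla g}}, with the gradient by central
#' differences. `transform` may return a vector, in which case one SE per
#' component is returned.
#'
#' @param transform function mapping the working parameter vector to the
#'   quantity (or quantities) of interest.
#' @param at working-scale point (typically the MLE).
#' @param covariance working-scale covariance matrix.
#' @param rel_step relative finite-difference step.
#' @return numeric vector of standard errors.
#' @export
delta_method_se <- function(transform, at, covariance, rel_step = 1e-6) {
  g0 <- transform(at)
  p <- length(at); q <- length(g0)
  J <- matrix(0, q, p)
  h <- rel_step * pmax(1, abs(at))
  for (i in seq_len(p)) {
    xp <- at; xp[i] <- xp[i] + h[i]
    xm <- at; xm[i] <- xm[i] - h[i]
    J[, i] <- (transform(xp) - transform(xm)) / (2 * h[i])
  }
  se <- sqrt(pmax(0, rowSums((J %*% covariance) * J)))
  names(se) <- names(g0)
  se
}

## data-driven starting values (documented in the methods vignette):
## per-area Poisson GLM of the increments on the design with a
## log-exposure offset, restricted to ever-damaged patients, seeds
## log lambda0 and beta (falling back to events per person-year and 0);
## stayer intercepts come from the per-area damage-free fraction through
## the complementary log-log inverse; dispersions and frailty variances
## start at 1.
default_init <- function(prep, model, layout) {
  w <- stats::setNames(numeric(length(layout$names)), layout$names)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  for (a in seq_along(AREA_NAMES)) {
    k <- AREA_NAMES[a]
    ar <- prep$areas[[k]]
    ever <- prep$cstar[, a] == 1
    use <- ever[ar$pid1]
    rate <- if (any(use) && sum(ar$dt[use]) > 0)
      sum(ar$d[use]) / sum(ar$dt[use]) else 0.1
    w[paste0(k, ":log_lambda0")] <- log(clamp(rate, 1e-3, 100))
    glm_init <- tryCatch({
      co <- stats::coef(suppressWarnings(stats::glm.fit(
        cbind(1, ar$Z[use, , drop = FALSE]), ar$d[use],
        offset = log(ar$dt[use]), family = stats::poisson())))
      if (all(is.finite(co))) co else NULL
    }, error = function(e) NULL)
    if (!is.null(glm_init) && sum(use) > 10 * length(glm_init)) {
      w[paste0(k, ":log_lambda0")] <- clamp(glm_init[1L], log(1e-3),
                                            log(100))
      w[paste0(k, ":b_", beta_names(model))] <-
        clamp(glm_init[-1L], -2, 2)
    }
    if (layout$free_theta) w[paste0(k, ":log_theta")] <- 0
    if (layout$with_stayer) {
      f0 <- clamp(mean(!ever), 0.02, 0.98)
      w[paste0(k, ":a1_(Intercept)")] <- log(-log(1 - f0))
    }
    if (model$variant == "twolevel")
      w[paste0(k, ":a2_(Intercept)")] <- log(-log(0.95))
    if (layout$has_preclinic) {
      gap_ok <- prep$onset_gap > 0
      pre_rate <- if (any(gap_ok))
        sum(prep$n0[gap_ok, a]) / sum(prep$onset_gap[gap_ok]) else 0.1
      w[paste0(k, ":log_lambda0_pre")] <- log(clamp(pre_rate, 1e-3, 100))
      if (layout$free_theta) w[paste0(k, ":log_theta_pre")] <- 0
    }
  }
  w
}

#' Fit a trivariate mover-stayer model by maximum likelihood
#'
#' Maximises the analytic marginal log-likelihood over the unconstrained
#' working parameters (log scale for intensities, dispersions and frailty
#' variances; identity for regression coefficients) with the BFGS
#' quasi-Newton algorithm. Standard errors come from the inverted observed
#' information matrix; marginal stayer probabilities per area are reported
#' with delta-method standard errors.
#'
#' @param data an `ms_data` object (see [visits_data()]).
#' @param model an `ms_model` spec.
#' @param init optional starting values: an `ms_params` object or a named
#'   working-scale vector. Defaults to crude data-driven values.
#' @param control list: `maxit` (default 500), `reltol` (default 1e-10),
#'   `se` (compute the information matrix, default TRUE), `nstart`
#'   (jittered multi-start count, default 1, recommended > 1 for the
#'   two-level variant), `jitter_sd` (default 0.3), `seed` (for the
#'   multi-start jitter only).
#' @return an object of class `ms_fit`: estimates on working and natural
#'   scales, maximised log-likelihood, covariance, Wald intervals, derived
#'   stayer probabilities, and convergence diagnostics. Non-convergence is
#'   flagged in `$diagnostics`, not thrown.
#' @export
fit_ms <- function(data, model = ms_model(), init = NULL, control = list()) {
  ctl <- utils::modifyList(list(maxit = 500L, reltol = 1e-10, se = TRUE,
                                nstart = 1L, jitter_sd = 0.3, seed = NULL),
                           control)
  prep <- prepare_data(data, model)
  model$preclinic <- prep$has_preclinic
  layout <- param_layout(model, prep$has_preclinic)
  p <- length(layout$names)

  w0 <- if (is.null(init)) default_init(prep, model, layout)
        else if (inherits(init, "ms_params")) pack_params(init, layout)
        else { stopifnot(length(init) == p); stats::setNames(init, layout$names) }

  ll <- function(w) {
    out <- tryCatch(suppressWarnings(
      dataset_loglik_prepared(prep, unpack_params(w, layout), model)),
      error = function(e) -Inf)
    if (!is.finite(out)) -1e10 else out
  }
  nll <- function(w) -ll(w)

  starts <- list(w0)
  if (ctl$nstart > 1L) {
    if (!is.null(ctl$seed)) set.seed(ctl$seed)
    for (s in seq_len(ctl$nstart - 1L))
      starts[[s + 1L]] <- w0 + stats::rnorm(p, sd = ctl$jitter_sd)
  }
  best <- NULL
  for (w_start in starts) {
    opt <- stats::optim(w_start, nll, method = "BFGS",
                        control = list(maxit = ctl$maxit,
                                       reltol = ctl$reltol))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  opt <- best
  what <- stats::setNames(opt$par, layout$names)
  params_hat <- unpack_params(what, layout)

  grad <- vapply(seq_len(p), function(i) {
    h <- 1e-6 * max(1, abs(what[i]))
    xp <- what; xp[i] <- xp[i] + h
    xm <- what; xm[i] <- xm[i] - h
    (ll(xp) - ll(xm)) / (2 * h)
  }, numeric(1))

  vcov_w <- matrix(NA_real_, p, p, dimnames = list(layout$names,
                                                   layout$names))
  se_w <- rep(NA_real_, p)
  if (isTRUE(ctl$se)) {
    info <- tryCatch(observed_information(ll, what),
                     error = function(e) NULL)
    if (!is.null(info)) {
      vcov_w <- invert_information(info)
      dimnames(vcov_w) <- list(layout$names, layout$names)
      se_w <- sqrt(pmax(0, diag(vcov_w)))
    }
  }

  z <- stats::qnorm(0.975)
  is_log <- grepl(":log_|^log_", layout$names)
  natural <- ifelse(is_log, exp(what), what)
  lower_w <- what - z * se_w
  upper_w <- what + z * se_w
  estimates <- data.frame(
    parameter = sub("^.*:log_|^log_", "",
                    sub(":b_", ":", sub(":a1_", ":alpha1 ",
                                        sub(":a2_", ":alpha2 ",
                                            layout$names)))),
    working = unname(what), se_working = se_w,
    estimate = unname(natural),
    lower = unname(ifelse(is_log, exp(lower_w), lower_w)),
    upper = unname(ifelse(is_log, exp(upper_w), upper_w)),
    row.names = layout$names, stringsAsFactors = FALSE)

  derived <- NULL
  if (layout$with_stayer) {
    pi_fn <- function(w) {
      pp <- unpack_params(w, layout)
      vapply(AREA_NAMES, function(k) {
        lp <- pp$alpha1[[k]][["(Intercept)"]]
        if (model$frailty == "gamma") stayer_prob_gamma(lp, pp$gamma)
        else stayer_prob_invgauss(lp, pp$gamma)
      }, numeric(1))
    }
    pi1 <- pi_fn(what)
    pi1_se <- if (all(is.finite(se_w)))
      delta_method_se(pi_fn, what, vcov_w) else rep(NA_real_, 3)
    derived <- data.frame(area = AREA_NAMES, pi1 = pi1, se = pi1_se,
                          lower = pi1 - z * pi1_se,
                          upper = pi1 + z * pi1_se,
                          row.names = NULL)
    if (model$variant == "twolevel") {
      pi2_fn <- function(w) {
        pp <- unpack_params(w, layout)
        vapply(AREA_NAMES, function(k) {
          lp <- pp$alpha2[[k]][["(Intercept)"]]
          if (model$frailty2 == "gamma") stayer_prob_gamma(lp, pp$gamma2)
          else stayer_prob_invgauss(lp, pp$gamma2)
        }, numeric(1))
      }
      derived$pi2 <- pi2_fn(what)
      derived$pi2_se <- if (all(is.finite(se_w)))
        delta_method_se(pi2_fn, what, vcov_w) else NA_real_
    }
  }

  structure(list(
    coefficients = what, estimates = estimates, params = params_hat,
    loglik = -opt$value, vcov = vcov_w, derived = derived,
    model = model, layout = layout, n_patients = prep$npat,
    diagnostics = list(convergence = opt$convergence,
                       converged = opt$convergence == 0L,
                       counts = opt$counts,
                       grad_norm = sqrt(sum(grad^2)),
                       boundary = any(abs(what) > 30),
                       message = opt$message)),
    class = "ms_fit")
}

#' @export
print.ms_fit <- function(x, ...) {
  cat(sprintf("Trivariate mover-stayer fit (variant '%s', %d patients)\n",
              x$model$variant, x$n_patients))
  cat(sprintf("Log-likelihood %.2f over %d parameters; %s\n", x$loglik,
              length(x$coefficients),
              if (x$diagnostics$converged) "converged"
              else sprintf("NOT converged (code %d)",
                           x$diagnostics$convergence)))
  if (x$diagnostics$boundary)
    cat("Note: some working parameters are at/near a boundary (|w| > 30)\n")
  est <- x$estimates
  print(data.frame(estimate = signif(est$estimate, 3),
                   lower = signif(est$lower, 3),
                   upper = signif(est$upper, 3),
                   row.names = rownames(est)))
  if (!is.null(x$derived)) {
    cat("\nMarginal stayer probabilities (delta-method SEs):\n")
    print(data.frame(lapply(x$derived,
                            function(c) if (is.numeric(c)) signif(c, 3)
                                        else c)))
  }
  invisible(x)
}

#' @export
coef.ms_fit <- function(object, ...) object$coefficients

#' @export
logLik.ms_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
vcov.ms_fit <- function(object, ...) object$vcov

#' Profile log-likelihood over one working parameter
#'
#' Fixes one working-scale parameter at each grid value and re-maximises
#' the log-likelihood over all remaining parameters, warm-starting each
#' grid point from its neighbour's solution. Used as an identifiability
#' diagnostic (e.g. for clinic-induced stayer intercepts and the
#' log variance of the second frailty).
#'
#' @param data an `ms_data` object.
#' @param model an `ms_model` spec.
#' @param target name of the working parameter to profile (see
#'   `names(coef(fit))`).
#' @param grid numeric vector of working-scale values.
#' @param init optional starting values (an `ms_fit`, `ms_params`, or
#'   working vector).
#' @param control passed to the inner fits ([fit_ms()] control minus
#'   `se`).
#' @return data frame of class `ms_profile` with columns `value`,
#'   `loglik`, `converged`.
#' @export
profile_loglik <- function(data, model, target, grid, init = NULL,
                           control = list()) {
  prep <- prepare_data(data, model)
  model$preclinic <- prep$has_preclinic
  layout <- param_layout(model, prep$has_preclinic)
  idx <- match(target, layout$names)
  if (is.na(idx))
    stop("unknown parameter '", target, "'; available: ",
         paste(layout$names, collapse = ", "), call. = FALSE)
  ctl <- utils::modifyList(list(maxit = 500L, reltol = 1e-10), control)

  w_cur <- if (inherits(init, "ms_fit")) init$coefficients
           else if (inherits(init, "ms_params")) pack_params(init, layout)
           else if (!is.null(init)) init
           else default_init(prep, model, layout)

  ll <- function(w) {
    out <- tryCatch(suppressWarnings(
      dataset_loglik_prepared(prep, unpack_params(w, layout), model)),
      error = function(e) -Inf)
    if (!is.finite(out)) -1e10 else out
  }
  res <- data.frame(value = grid, loglik = NA_real_, converged = NA)
  free <- setdiff(seq_along(layout$names), idx)
  for (g in seq_along(grid)) {
    nll_g <- function(wf) {
      w <- numeric(length(layout$names))
      w[free] <- wf; w[idx] <- grid[g]
      -ll(w)
    }
    opt <- stats::optim(w_cur[free], nll_g, method = "BFGS",
                        control = list(maxit = ctl$maxit,
                                       reltol = ctl$reltol))
    res$loglik[g] <- -opt$value
    res$converged[g] <- opt$convergence == 0L
    w_cur[free] <- opt$par; w_cur[idx] <- grid[g]
  }
  class(res) <- c("ms_profile", "data.frame")
  attr(res, "target") <- target
  res
}

#' @export
plot.ms_profile <- function(x, ...) {
  graphics::plot(x$value, x$loglik, type = "b", pch = 4,
                 xlab = attr(x, "target"),
                 ylab = "profile log-likelihood", ...)
  invisible(x)
}
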