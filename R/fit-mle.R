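# Maximum-likelihood fitting of fixed-effect SDE models and the two
# three-or-fewer-parameter baselines they are compared against.

new_growth_fit <- function(family, estimates, standard_errors, loglik,
                           n_params, n_obs, converged,
                           transformed = NULL, vcov = NULL, fitspec = NULL,
                           children = NULL, site_of_child = NULL,
                           random_effects_cov_hat = NULL,
                           empirical_bayes = NULL, details = list()) {
  structure(list(family = family,
                 estimates = estimates,
                 standard_errors = standard_errors,
                 loglik = loglik,
                 n_params = n_params,
                 n_obs = n_obs,
                 aic = 2 * n_params - 2 * loglik,
                 bic = n_params * log(n_obs) - 2 * loglik,
                 converged = converged,
                 transformed = transformed,
                 vcov = vcov,
                 fitspec = fitspec,
                 children = children,
                 site_of_child = site_of_child,
                 random_effects_cov_hat = random_effects_cov_hat,
                 empirical_bayes = empirical_bayes,
                 details = details),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("%s fit%s\n", x$family,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(estimate = x$estimates,
                    std_error = x$standard_errors[names(x$estimates)])
  print(round(tab, 5))
  cat(sprintf("logLik %.3f | params %d | n_obs %d | AIC %.2f | BIC %.2f\n",
              x$loglik, x$n_params, x$n_obs, x$aic, x$bic))
  if (!is.null(x$random_effects_cov_hat)) {
    cat("random-effects covariance:\n")
    print(round(x$random_effects_cov_hat, 5))
  }
  invisible(x)
}

#' @export
logLik.growth_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' Wald tests for the fitted parameters
#'
#' z statistics and two-sided p-values from the observed-information
#' standard errors, used by [model_search()] to trim weak terms.
#'
#' @param fit a `growth_fit`.
#' @return data.frame with columns `estimate`, `std_error`, `z`, `p_value`.
#' @export
wald_table <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  est <- fit$estimates
  se <- fit$standard_errors[names(est)]
  z <- est / se
  data.frame(term = names(est), estimate = unname(est),
             std_error = unname(se), z = unname(z),
             p_value = unname(2 * stats::pnorm(-abs(z))),
             row.names = NULL)
}

# shared optimisation driver: multi-start bounded quasi-Newton on the
# transformed scale, observed-information standard errors
optimize_fit <- function(obj, init, fitspec, options) {
  restarts <- options$restarts %||% 5L
  jitter_sd <- options$jitter_sd %||% 0.4
  restart_seed <- options$restart_seed %||% 20231L
  ctrl <- list(eval.max = options$eval.max %||% 4000L,
               iter.max = options$iter.max %||% 2000L,
               rel.tol = options$rel.tol %||% 1e-10)
  starts <- list(init)
  for (st in options$extra_starts %||% list()) starts <- c(starts, list(st))
  if (restarts > 1L) {
    jit <- with_private_seed(restart_seed, {
      lapply(seq_len(restarts - 1L),
             function(r) stats::rnorm(length(init), 0, jitter_sd))
    })
    for (j in jit) starts <- c(starts, list(init + j))
  }
  best <- NULL
  for (st in starts) {
    res <- tryCatch(stats::nlminb(st, obj, control = ctrl),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    if (is.null(best) || res$objective < best$objective - 1e-10) best <- res
  }
  if (is.null(best))
    return(list(par = init, objective = obj(init), converged = FALSE,
                vcov = NULL, se = rep(NA_real_, length(init))))
  H <- tryCatch(stats::optimHess(best$par, obj,
                                 control = list(ndeps = rep(1e-5,
                                                            length(init)))),
                error = function(e) NULL)
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
  se <- if (!is.null(vc)) {
    d <- diag(vc)
    ifelse(d > 0, sqrt(pmax(d, 0)), NA_real_)
  } else rep(NA_real_, length(init))
  ok <- best$convergence == 0 ||
    grepl("relative convergence|X-convergence|both X", best$message %||% "")
  list(par = stats::setNames(best$par, fitspec$par_names),
       objective = best$objective,
       converged = ok,
       vcov = vc, se = stats::setNames(se, fitspec$par_names),
       message = best$message)
}

#' Fit an SDE model by transition maximum likelihood
#'
#' Minimises the summed per-child negative transition log-likelihood over
#' the free parameters of the model template.  The diffusion `s` (and, in
#' the OU parameterisation, the reversion speed `alpha`) is optimised on the
#' log scale; drift coefficients are unconstrained in sign in the natural
#' parameterisation.  Optimisation is multi-start (default 5 restarts from
#' jittered moment-matching initials, fixed restart seeds) and standard
#' errors come from the observed information (finite-difference Hessian).
#'
#' @param model_template an [sde_model()] defining the family (drift order,
#'   mean reversion); its parameter values are ignored, only the structure
#'   matters.  If it carries `site_offsets`, per-site offsets for those
#'   parameters are estimated (reference = first site in the cohort).
#' @param cohort a `growth_cohort` data.frame; every child needs >= 2
#'   visits.
#' @param parameterization `"natural"` (free-sign `a1`) or `"ou"`
#'   (`log alpha, beta, log sigma`; requires an OU-structured template).
#' @param options list: `restarts`, `jitter_sd`, `restart_seed`, `init`
#'   (transformed-scale starting values), `rel.tol`, ...
#' @return a `growth_fit` with natural-scale `estimates`,
#'   `standard_errors`, `loglik`, `n_params`, `aic`, `bic`, `converged`
#'   (AIC = 2k - 2logL, BIC = k log(n_obs) - 2logL with `n_obs` the total
#'   visit count).
#' @examples
#' \donttest{
#' set.seed(1)
#' coh <- simulate_cohort(ou_model(1, -0.5, 0.6),
#'                        cohort_design(30, sites = "A", seed = 1))
#' fit_mle(ou_model(1, 0, 1), coh, parameterization = "ou")
#' }
#' @export
fit_mle <- function(model_template, cohort,
                    parameterization = c("natural", "ou"),
                    options = list()) {
  stopifnot(inherits(model_template, "sde_model"))
  parameterization <- match.arg(parameterization)
  trans <- build_transitions(cohort)
  fitspec <- make_fitspec(model_template, unique(trans$site_of_child),
                          parameterization = parameterization,
                          site_param_names = names(model_template$site_offsets),
                          dropped = options$dropped %||% character())
  obj <- function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 50)) return(1e10)
    P <- fs_child_params(fitspec, theta, trans$site_of_child)
    v <- nll_transitions(trans, P)
    if (!is.finite(v)) 1e10 else v
  }
  init <- options$init %||% fs_init(fitspec, trans)
  opt <- optimize_fit(obj, init, fitspec, options)
  nat <- fs_natural(fitspec, opt$par, opt$se)
  new_growth_fit(
    family = if (parameterization == "ou") "SDE (OU, maximum likelihood)"
             else "SDE (maximum likelihood)",
    estimates = nat$estimates, standard_errors = nat$standard_errors,
    loglik = -opt$objective, n_params = fitspec$n_par, n_obs = trans$n_obs,
    converged = opt$converged, transformed = opt$par, vcov = opt$vcov,
    fitspec = fitspec, children = trans$children,
    site_of_child = trans$site_of_child,
    details = list(message = opt$message))
}

#' Simple baselines: transition and global linear regression
#'
#' Two three-or-fewer-parameter reference models.  `"transition"` is the
#' naive linear transition model
#' \eqn{X_1 \mid X_0 \sim N(X_0 + b(t_1 - t_0), \sigma^2)} — constant growth
#' velocity `b` and an elapsed-time-independent variance — with 2
#' parameters.  `"global"` is the classical curve-fitting regression
#' \eqn{X(t) \sim N(a_0 + a_1 t, \sigma^2)} (3 parameters), fitted across
#' all observations by ordinary least squares.
#'
#' @param cohort a `growth_cohort` data.frame.
#' @param type which baseline.
#' @return a `growth_fit` (AIC/BIC comparable with [fit_mle()] on the same
#'   cohort).
#' @export
fit_linear_baseline <- function(cohort, type = c("transition", "global")) {
  type <- match.arg(type)
  if (type == "transition") {
    trans <- build_transitions(cohort)
    dt <- trans$t1 - trans$t0
    dx <- trans$x1 - trans$x0
    b <- sum(dx * dt) / sum(dt^2)
    resid <- dx - b * dt
    n <- length(dx)
    sig2 <- mean(resid^2)
    ll <- sum(stats::dnorm(dx, b * dt, sqrt(sig2), log = TRUE))
    est <- c(b = b, sigma = sqrt(sig2))
    se <- c(b = sqrt(sig2 / sum(dt^2)), sigma = sqrt(sig2) / sqrt(2 * n))
    new_growth_fit("linear transition baseline", est, se, ll,
                   n_params = 2L, n_obs = trans$n_obs, converged = TRUE)
  } else {
    cohort <- as.data.frame(cohort)
    fit <- stats::lm(zwfl ~ age_months, data = cohort)
    n <- nrow(cohort)
    sig2 <- mean(stats::residuals(fit)^2)
    ll <- as.numeric(stats::logLik(fit))
    cf <- stats::coef(fit)
    cse <- sqrt(diag(stats::vcov(fit)))
    est <- c(a0 = unname(cf[1L]), a1 = unname(cf[2L]), sigma = sqrt(sig2))
    se <- c(a0 = unname(cse[1L]), a1 = unname(cse[2L]),
            sigma = sqrt(sig2) / sqrt(2 * n))
    new_growth_fit("global linear regression", est, se, ll,
                   n_params = 3L, n_obs = n, converged = TRUE)
  }
}
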