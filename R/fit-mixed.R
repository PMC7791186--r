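# Mixed-effects SDE fitting: child-level Gaussian random effects on model
# parameters, marginal likelihood by adaptive Gauss-Hermite quadrature
# (Laplace approximation beyond 2 random-effect dimensions).
#
# For child i with random effect b_i ~ N(0, Sigma_b), the marginal
# likelihood contribution is  integral exp(-nll_i(theta, b)) phi(b; 0,
# Sigma_b) db.  Writing g_i(b) = nll_i(theta, b) + b' Sigma^-1 b / 2 +
# log|2 pi Sigma| / 2, the integral is  int exp(-g_i) db, approximated
# around the per-child mode with curvature-rescaled Hermite nodes.

# Gauss-Hermite nodes/weights (weight function exp(-z^2)) via the Jacobi
# matrix eigen-decomposition
gauss_hermite <- function(n) {
  n <- as.integer(n)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  b <- sqrt(seq_len(n - 1L) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- b
  J[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1L, ord]^2)
}

logsumexp_rows <- function(M) {
  mx <- apply(M, 1L, max)
  mx + log(rowSums(exp(M - mx)))
}

# One-dimensional case: damped Newton for all children's modes at once
# (every function evaluation is a single vectorised likelihood pass).
inner_modes_1d <- function(f, b0, sig2, maxit = 25L, tol = 3e-6) {
  b <- b0
  f0 <- f(b)
  for (it in seq_len(maxit)) {
    h <- 1e-4 * (1 + abs(b))
    fp <- f(b + h)
    fm <- f(b - h)
    g <- (fp - fm) / (2 * h)
    H <- (fp - 2 * f0 + fm) / h^2
    H[!is.finite(H) | H <= 0] <- 1 / sig2
    step <- -g / H
    step <- pmin(pmax(step, -3 * sqrt(sig2) - 1), 3 * sqrt(sig2) + 1)
    bn <- b + step
    fn <- f(bn)
    for (bt in 1:6) {
      worse <- !is.finite(fn) | fn > f0 + 1e-12
      if (!any(worse)) break
      bn[worse] <- (b[worse] + bn[worse]) / 2
      fn <- f(bn)
    }
    worse <- !is.finite(fn) | fn > f0
    bn[worse] <- b[worse]
    fn[worse] <- f0[worse]
    done <- max(abs(g)) < tol
    b <- bn
    f0 <- fn
    if (done) break
  }
  h <- 1e-4 * (1 + abs(b))
  fp <- f(b + h)
  fm <- f(b - h)
  A <- (fp - 2 * f0 + fm) / h^2
  A[!is.finite(A) | A <= 0] <- 1 / sig2
  list(mode = b, f_mode = f0, curvature = A)
}

# builder for the marginal negative log-likelihood; keeps a warm-start
# cache of the per-child modes across outer optimiser evaluations
make_mixed_objective <- function(fitspec, trans, nodes = 5L,
                                 method = NULL) {
  d <- fitspec$d
  if (is.null(method)) method <- if (d <= 2L) "agq" else "laplace"
  gh <- gauss_hermite(nodes)
  n_children <- trans$n_children
  child_rows <- split(seq_along(trans$child), trans$child)
  cache <- new.env(parent = emptyenv())
  cache$B <- matrix(0, n_children, d)

  nll_child <- function(theta, B) {
    P <- fs_child_params(fitspec, theta, trans$site_of_child, B)
    nll_transitions(trans, P, per_child = TRUE)
  }

  eval_children <- function(theta, want_modes = FALSE) {
    Sig <- fs_re_cov(fitspec, theta)
    if (d == 1L) {
      sig2 <- Sig[1L, 1L]
      logdet_pen <- 0.5 * log(2 * pi * sig2)
      f <- function(b) nll_child(theta, matrix(b, ncol = 1L)) +
        0.5 * b^2 / sig2 + logdet_pen
      if (sqrt(sig2) < 1e-7) {
        # degenerate random effect: the mixture collapses onto b = 0
        logI <- -nll_child(theta, matrix(0, n_children, 1L))
        return(list(logI = logI, modes = matrix(0, n_children, 1L),
                    curvature = rep(1 / max(sig2, 1e-300), n_children)))
      }
      mo <- inner_modes_1d(f, cache$B[, 1L], sig2)
      cache$B <- matrix(mo$mode, ncol = 1L)
      if (method == "laplace" || nodes == 1L) {
        logI <- -mo$f_mode + 0.5 * log(2 * pi) - 0.5 * log(mo$curvature)
      } else {
        sc <- sqrt(2 / mo$curvature)
        Fm <- vapply(seq_along(gh$nodes),
                     function(j) f(mo$mode + sc * gh$nodes[j]),
                     numeric(n_children))
        E <- sweep(-Fm, 2L, log(gh$weights) + gh$nodes^2, `+`)
        logI <- 0.5 * log(2) - 0.5 * log(mo$curvature) + logsumexp_rows(E)
      }
      list(logI = logI, modes = matrix(mo$mode, ncol = 1L),
           curvature = mo$curvature)
    } else {
      Sinv <- tryCatch(solve(Sig), error = function(e) NULL)
      if (is.null(Sinv))
        return(list(logI = rep(-Inf, n_children)))
      ldet <- determinant(Sig, logarithm = TRUE)$modulus
      pen_const <- 0.5 * (d * log(2 * pi) + as.numeric(ldet))
      logI <- numeric(n_children)
      modes <- matrix(0, n_children, d)
      for (i in seq_len(n_children)) {
        rows <- child_rows[[i]]
        site_i <- trans$site_of_child[i]
        gi <- function(b) {
          P <- fs_child_params(fitspec, theta, site_i,
                               matrix(b, 1L, d))
          mo <- slice_moments(trans$t0[rows], trans$t1[rows],
                              trans$x0[rows], P[1L, 1L], P[1L, 2L],
                              P[1L, 3L], P[1L, 4L], P[1L, 5L], P[1L, 6L])
          -sum(stats::dnorm(trans$x1[rows], mo$mean, sqrt(mo$var),
                            log = TRUE)) +
            0.5 * drop(b %*% Sinv %*% b) + pen_const
        }
        op <- stats::nlminb(cache$B[i, ], gi,
                            control = list(rel.tol = 1e-11))
        mu <- op$par
        A <- tryCatch(stats::optimHess(mu, gi,
                                       control = list(ndeps = rep(1e-4, d))),
                      error = function(e) Sinv)
        eA <- eigen(A, symmetric = TRUE)
        if (any(eA$values <= 0)) A <- Sinv
        modes[i, ] <- mu
        if (method == "laplace" || d > 2L) {
          logI[i] <- -op$objective + 0.5 * d * log(2 * pi) -
            0.5 * as.numeric(determinant(A, logarithm = TRUE)$modulus)
        } else {
          # tensor-product adaptive nodes
          Ainv <- solve(A)
          Lh <- chol(Ainv)
          grid <- as.matrix(expand.grid(rep(list(seq_along(gh$nodes)), d)))
          vals <- apply(grid, 1L, function(jj) {
            z <- gh$nodes[jj]
            lw <- sum(log(gh$weights[jj]) + z^2)
            b <- mu + sqrt(2) * drop(t(Lh) %*% z)
            lw - gi(b)
          })
          mx <- max(vals)
          logI[i] <- 0.5 * d * log(2) -
            0.5 * as.numeric(determinant(A, logarithm = TRUE)$modulus) +
            mx + log(sum(exp(vals - mx)))
        }
      }
      cache$B <- modes
      list(logI = logI, modes = modes)
    }
  }

  list(
    nll = function(theta) {
      if (any(!is.finite(theta)) || any(abs(theta) > 50)) return(1e10)
      out <- tryCatch(-sum(eval_children(theta)$logI),
                      error = function(e) 1e10)
      if (!is.finite(out)) 1e10 else out
    },
    modes = function(theta) eval_children(theta, want_modes = TRUE)$modes)
}

#' Fit a mixed-effects SDE model
#'
#' Maximises the marginal likelihood
#' \deqn{\prod_i \int L_i(\theta, b_i)\, \phi(b_i; 0, \Sigma_b)\, db_i}
#' over the fixed parameters and the child-level random-effects covariance
#' \eqn{\Sigma_b}.  The integral is approximated by adaptive Gauss-Hermite
#' quadrature (default 5 nodes per dimension), or by the Laplace
#' approximation when more than two parameters carry random effects.
#' \eqn{\Sigma_b} is parameterised through its Cholesky factor with log
#' diagonal, so every optimiser iterate is a valid covariance.  Random
#' effects on `s` (natural parameterisation) or on `alpha`/`sigma` (OU
#' parameterisation) act on the log scale.
#'
#' @inheritParams fit_mle
#' @param re_names non-empty character vector of parameters carrying random
#'   effects: subset of the drift coefficients and `"s"` (natural), or of
#'   `c("alpha", "beta", "sigma")` (OU).
#' @param re_cov_structure `"diagonal"` or `"unstructured"`.
#' @param options additionally: `nodes` (quadrature nodes per dimension,
#'   default 5), `method` (`"agq"` or `"laplace"`), `fix_re_zero` (constrain
#'   \eqn{\Sigma_b = 0}, reproducing [fit_mle()]).
#' @return a `growth_fit` with, additionally, `random_effects_cov_hat` and
#'   `empirical_bayes` (per-child posterior modes \eqn{\hat b_i}, one named
#'   row per child).
#' @export
fit_mixed_sde <- function(model_template, cohort, re_names,
                          re_cov_structure = c("diagonal", "unstructured"),
                          parameterization = c("natural", "ou"),
                          options = list()) {
  stopifnot(inherits(model_template, "sde_model"))
  re_cov_structure <- match.arg(re_cov_structure)
  parameterization <- match.arg(parameterization)
  if (isTRUE(options$fix_re_zero)) {
    fit <- fit_mle(model_template, cohort, parameterization, options)
    d <- length(re_names)
    fit$family <- "SDE (mixed effects, Sigma_b = 0)"
    fit$random_effects_cov_hat <- matrix(0, d, d,
                                         dimnames = list(re_names, re_names))
    eb <- matrix(0, length(fit$children), d,
                 dimnames = list(fit$children, re_names))
    fit$empirical_bayes <- as.data.frame(eb)
    return(fit)
  }
  if (length(re_names) == 0L)
    stop("'re_names' must be a non-empty subset of the model parameters")
  trans <- build_transitions(cohort)
  fitspec <- make_fitspec(model_template, unique(trans$site_of_child),
                          parameterization = parameterization,
                          site_param_names = names(model_template$site_offsets),
                          re_names = re_names, re_cov = re_cov_structure,
                          dropped = options$dropped %||% character())
  mk <- make_mixed_objective(fitspec, trans,
                             nodes = options$nodes %||% 5L,
                             method = options$method)
  init <- options$init
  if (is.null(init)) {
    # start the fixed part at the fixed-effects MLE: cheap, and it puts the
    # outer optimiser straight into the marginal likelihood's basin
    init <- fs_init(fitspec, trans)
    fx <- tryCatch(
      fit_mle(model_template, cohort, parameterization,
              options = utils::modifyList(options,
                                          list(restarts = 2L,
                                               dropped = options$dropped %||%
                                                 character()))),
      error = function(e) NULL)
    if (!is.null(fx) && all(is.finite(fx$transformed)))
      init[seq_along(fx$transformed)] <- fx$transformed
    # a pooled fixed-effects start can sit in the wrong basin when the
    # between-child spread is large; always try the within-child
    # moment-matching start as well
    options$extra_starts <- c(options$extra_starts,
                              list(fs_init_within(fitspec, trans)))
  }
  options$restarts <- options$restarts %||% 2L
  options$jitter_sd <- options$jitter_sd %||% 0.15
  opt <- optimize_fit(mk$nll, init, fitspec, options)
  nat <- fs_natural(fitspec, opt$par, opt$se)
  Sig_hat <- fs_re_cov(fitspec, opt$par)
  B <- mk$modes(opt$par)
  dimnames(B) <- list(trans$children, re_names)
  new_growth_fit(
    family = "SDE (mixed effects)",
    estimates = nat$estimates, standard_errors = nat$standard_errors,
    loglik = -opt$objective, n_params = fitspec$n_par, n_obs = trans$n_obs,
    converged = opt$converged, transformed = opt$par, vcov = opt$vcov,
    fitspec = fitspec, children = trans$children,
    site_of_child = trans$site_of_child,
    random_effects_cov_hat = Sig_hat,
    empirical_bayes = as.data.frame(B),
    details = list(message = opt$message, trans = trans,
                   nodes = options$nodes %||% 5L))
}

#' Empirical-Bayes random-effect modes for a cohort
#'
#' Posterior modes \eqn{\hat b_i} of the child-level random effects under
#' the fitted parameters, for the fit's own cohort or for modified data
#' (e.g. truncated trajectories) evaluated at the same parameters.
#'
#' @param fit a mixed `growth_fit` from [fit_mixed_sde()].
#' @param cohort optional `growth_cohort`; defaults to the fitting data.
#' @return data.frame of modes, one named row per child.
#' @export
empirical_bayes_modes <- function(fit, cohort = NULL) {
  stopifnot(inherits(fit, "growth_fit"), fit$fitspec$d > 0L)
  trans <- if (is.null(cohort)) fit$details$trans
           else build_transitions(cohort)
  mk <- make_mixed_objective(fit$fitspec, trans,
                             nodes = fit$details$nodes %||% 5L)
  B <- mk$modes(fit$transformed)
  dimnames(B) <- list(trans$children, fit$fitspec$re_names)
  as.data.frame(B)
}

#' Re-evaluate a mixed fit's marginal negative log-likelihood
#'
#' Evaluates the adaptive Gauss-Hermite marginal negative log-likelihood at
#' the fitted parameters with a chosen number of quadrature nodes — useful
#' for checking quadrature accuracy (e.g. 5 vs 21 nodes).
#'
#' @param fit a mixed `growth_fit` from [fit_mixed_sde()].
#' @param nodes quadrature nodes per dimension.
#' @return the marginal negative log-likelihood.
#' @export
mixed_marginal_negloglik <- function(fit, nodes = 5L) {
  stopifnot(inherits(fit, "growth_fit"), !is.null(fit$details$trans))
  mk <- make_mixed_objective(fit$fitspec, fit$details$trans, nodes = nodes,
                             method = "agq")
  mk$nll(fit$transformed)
}
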