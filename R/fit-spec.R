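# Internal parameter bookkeeping for fitting.
#
# A "fitspec" maps between the optimiser's unconstrained parameter vector
# theta and per-child natural parameters (a1..a5, s):
#   * natural parameterisation: drift coefficients free in sign, s = exp(log_s)
#   * "ou" parameterisation: (log_alpha, beta, log_s) with a1 = -alpha,
#     a2 = alpha * beta (constrains alpha > 0)
#   * per-site additive offsets for selected drift parameters, and log-scale
#     offsets for s, relative to the first (reference) site
#   * child-level random effects act additively on selected transformed
#     entries (so effects on s / alpha live on the log scale)
#   * the random-effects covariance is parameterised through its Cholesky
#     factor with log diagonal, so any theta yields a valid PSD matrix.

make_fitspec <- function(model_template, sites,
                         parameterization = c("natural", "ou"),
                         site_param_names = character(),
                         re_names = character(),
                         re_cov = c("diagonal", "unstructured"),
                         dropped = character()) {
  parameterization <- match.arg(parameterization)
  re_cov <- match.arg(re_cov)
  sites <- unique(as.character(sites))

  if (parameterization == "ou") {
    if (!(model_template$drift_order == 0L && model_template$mean_reversion))
      stop("the OU parameterisation requires drift_order 0 with mean ",
           "reversion")
    if (length(site_param_names))
      stop("site offsets are supported in the natural parameterisation only")
    base <- c("log_alpha", "beta", "log_s")
    re_map <- c(alpha = "log_alpha", beta = "beta", sigma = "log_s",
                s = "log_s")
  } else {
    drift_terms <- c(if (model_template$mean_reversion) "a1",
                     paste0("a", 2:(2 + model_template$drift_order)))
    drift_terms <- setdiff(drift_terms, dropped)
    if (!length(drift_terms))
      stop("no drift terms left in the model")
    base <- c(drift_terms, "log_s")
    re_map <- c(stats::setNames(drift_terms, drift_terms), s = "log_s")
  }
  bad <- setdiff(re_names, names(re_map))
  if (length(bad))
    stop("random effects requested on unknown parameter(s): ",
         paste(bad, collapse = ", "))
  bad_off <- setdiff(site_param_names,
                     c(setdiff(base, "log_s"), "s"))
  if (length(bad_off))
    stop("site offsets requested on unknown parameter(s): ",
         paste(bad_off, collapse = ", "))

  par_names <- base
  offset_idx <- list()
  if (length(site_param_names) && length(sites) > 1L) {
    for (p in site_param_names) {
      tn <- if (p == "s") "log_s" else p
      idx <- integer(0)
      for (st in sites[-1L]) {
        par_names <- c(par_names, paste0(tn, "@", st))
        idx <- c(idx, length(par_names))
      }
      names(idx) <- sites[-1L]
      offset_idx[[tn]] <- idx
    }
  }
  d <- length(re_names)
  gamma_idx <- integer(0)
  if (d > 0L) {
    n_gamma <- if (re_cov == "diagonal") d else d * (d + 1L) / 2L
    gnames <- if (re_cov == "diagonal") paste0("log_sd_", re_names)
              else paste0("chol_", seq_len(n_gamma))
    gamma_idx <- length(par_names) + seq_len(n_gamma)
    par_names <- c(par_names, gnames)
  }
  list(parameterization = parameterization,
       drift_order = model_template$drift_order,
       mean_reversion = model_template$mean_reversion,
       dropped = dropped,
       base = base,
       base_idx = stats::setNames(seq_along(base), base),
       offset_idx = offset_idx,
       sites = sites,
       site_param_names = site_param_names,
       re_names = re_names,
       re_entries = unname(re_map[re_names]),
       re_cov = re_cov,
       d = d,
       gamma_idx = gamma_idx,
       par_names = par_names,
       n_par = length(par_names))
}

# random-effects covariance from the gamma block of theta
fs_re_cov <- function(fitspec, theta) {
  d <- fitspec$d
  if (d == 0L) return(matrix(0, 0, 0))
  g <- theta[fitspec$gamma_idx]
  if (fitspec$re_cov == "diagonal") {
    Sig <- diag(exp(2 * g), d)
  } else {
    L <- matrix(0, d, d)
    k <- 0L
    for (i in seq_len(d)) for (j in seq_len(i)) {
      k <- k + 1L
      L[i, j] <- if (i == j) exp(g[k]) else g[k]
    }
    Sig <- L %*% t(L)
  }
  dimnames(Sig) <- list(fitspec$re_names, fitspec$re_names)
  Sig
}

# n_children x 6 natural parameter matrix (a1..a5, s); B is an optional
# n_children x d matrix of random effects on the transformed scale
fs_child_params <- function(fitspec, theta, site_of_child, B = NULL) {
  n <- length(site_of_child)
  nb <- length(fitspec$base)
  M <- matrix(theta[seq_len(nb)], n, nb, byrow = TRUE,
              dimnames = list(NULL, fitspec$base))
  if (!is.null(B) && fitspec$d > 0L) {
    for (j in seq_len(fitspec$d))
      M[, fitspec$re_entries[j]] <- M[, fitspec$re_entries[j]] + B[, j]
  }
  if (length(fitspec$offset_idx)) {
    for (tn in names(fitspec$offset_idx)) {
      idx <- fitspec$offset_idx[[tn]]
      for (st in names(idx)) {
        sel <- site_of_child == st
        if (any(sel)) M[sel, tn] <- M[sel, tn] + theta[idx[[st]]]
      }
    }
  }
  P <- matrix(0, n, 6L, dimnames = list(NULL,
                                        c("a1", "a2", "a3", "a4", "a5", "s")))
  if (fitspec$parameterization == "ou") {
    alpha <- exp(M[, "log_alpha"])
    P[, "a1"] <- -alpha
    P[, "a2"] <- alpha * M[, "beta"]
  } else {
    for (p in setdiff(fitspec$base, "log_s")) P[, p] <- M[, p]
  }
  P[, "s"] <- exp(M[, "log_s"])
  P
}

# moment-matching starting values: regress the observed per-transition rate
# (x1 - x0) / dt on the active drift design
fs_init <- function(fitspec, trans) {
  dt <- trans$t1 - trans$t0
  y <- (trans$x1 - trans$x0) / dt
  cols <- list(a2 = rep(1, length(y)), a3 = trans$t0, a4 = trans$t0^2,
               a5 = trans$t0^3, a1 = trans$x0)
  if (fitspec$parameterization == "ou") {
    X <- cbind(cols$a2, cols$a1)
    cf <- tryCatch(stats::lm.fit(X, y)$coefficients,
                   error = function(e) c(0, -0.5))
    cf[!is.finite(cf)] <- 0
    alpha0 <- max(0.05, -cf[2L])
    beta0 <- max(-5, min(5, cf[1L] / alpha0))
    fitted <- cf[1L] + cf[2L] * trans$x0
    theta <- c(log(alpha0), beta0, NA_real_)
  } else {
    active <- setdiff(fitspec$base, "log_s")
    X <- do.call(cbind, cols[active])
    cf <- tryCatch(stats::lm.fit(X, y)$coefficients,
                   error = function(e) rep(0, length(active)))
    cf[!is.finite(cf)] <- 0
    fitted <- drop(X %*% cf)
    theta <- c(cf, NA_real_)
  }
  resid <- trans$x1 - (trans$x0 + fitted * dt)
  s0 <- stats::sd(resid / sqrt(dt))
  theta[length(theta)] <- log(max(s0, 1e-3))
  theta <- c(theta, rep(0, fitspec$n_par - length(theta)))
  if (fitspec$d > 0L) {
    gi <- fitspec$gamma_idx
    if (fitspec$re_cov == "diagonal") theta[gi] <- log(0.3)
    else {
      k <- 0L
      for (i in seq_len(fitspec$d)) for (j in seq_len(i)) {
        k <- k + 1L
        theta[gi[k]] <- if (i == j) log(0.3) else 0
      }
    }
  }
  stats::setNames(theta, fitspec$par_names)
}

# within-child moment-matching start for mixed fits: per-child trajectory
# means estimate the spread of a random level, and regression of the
# observed rate on the child-centred state estimates the reversion speed
# without confounding it with between-child spread
fs_init_within <- function(fitspec, trans) {
  theta <- fs_init(fitspec, trans)
  xbar_c <- as.numeric(tapply(c(trans$x0, trans$x1),
                              c(trans$child, trans$child), mean))
  xbar <- xbar_c[trans$child]
  dt <- trans$t1 - trans$t0
  y <- (trans$x1 - trans$x0) / dt
  cf <- tryCatch(stats::lm.fit(cbind(trans$x0 - xbar), y)$coefficients,
                 error = function(e) -0.5)
  alpha0 <- max(0.05, -cf[[1L]])
  resid <- trans$x1 - trans$x0 - (cf[[1L]] * (trans$x0 - xbar)) * dt
  s0 <- max(stats::sd(resid / sqrt(dt)), 1e-3)
  spread <- max(stats::sd(xbar_c), 0.05)
  if (fitspec$parameterization == "ou") {
    theta[["log_alpha"]] <- log(alpha0)
    theta[["beta"]] <- mean(xbar_c)
    theta[["log_s"]] <- log(s0)
  } else {
    if ("a1" %in% fitspec$base) theta[["a1"]] <- -alpha0
    if ("a2" %in% fitspec$base) theta[["a2"]] <- alpha0 * mean(xbar_c)
    theta[["log_s"]] <- log(s0)
  }
  if (fitspec$d > 0L && fitspec$re_cov == "diagonal") {
    gi <- fitspec$gamma_idx
    for (j in seq_len(fitspec$d)) {
      ent <- fitspec$re_entries[j]
      theta[gi[j]] <- if (ent == "beta") log(spread)
        else if (ent == "a2") log(spread * alpha0)
        else log(0.3)
    }
  }
  theta
}

# natural-scale estimates and delta-method standard errors
fs_natural <- function(fitspec, theta, se) {
  est <- theta
  nm <- names(theta)
  out_nm <- nm
  for (i in seq_along(nm)) {
    if (nm[i] == "log_alpha") { out_nm[i] <- "alpha" }
    else if (nm[i] == "log_s") {
      out_nm[i] <- if (fitspec$parameterization == "ou") "sigma" else "s"
    }
    else if (startsWith(nm[i], "log_sd_")) out_nm[i] <- sub("^log_", "", nm[i])
    if (nm[i] %in% c("log_alpha", "log_s") || startsWith(nm[i], "log_sd_")) {
      est[i] <- exp(theta[i])
      se[i] <- est[i] * se[i]
    }
  }
  list(estimates = stats::setNames(est, out_nm),
       standard_errors = stats::setNames(se, out_nm))
}

# run a block of code with a private, seeded RNG stream, restoring the
# caller's stream afterwards (fits must not consume global randomness)
with_private_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}
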