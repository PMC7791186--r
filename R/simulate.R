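# Exact and approximate simulation, plus the synthetic-cohort generator.

DAYS_PER_MONTH <- 30.4375
JITTER_CAP_MONTHS <- 14 / DAYS_PER_MONTH  # visit window of +/- 14 days

#' Draw one exact transition from the slice density
#'
#' Samples \eqn{X_{t_1} \mid X_{t_0} = x_0} from the closed-form Gaussian
#' transition law of the model — an exact simulation step with no
#' discretisation error.  Uses R's global RNG stream, so results are
#' reproducible under [set.seed()].
#'
#' @inheritParams slice_density
#' @param n number of independent draws.
#' @return numeric vector of `n` draws (z-score units).
#' @export
sample_transition <- function(model, x0, t0, t1, site = NULL, n = 1L) {
  d <- slice_density(model, x0, t0, t1, site)
  if (d$variance == 0) rep(d$mean, n)
  else stats::rnorm(n, d$mean, sqrt(d$variance))
}

#' Euler-Maruyama endpoint simulation
#'
#' Discretised simulation of the SDE from `(t0, x0)` to `t1` with increments
#' \eqn{x \leftarrow x + \mu(t, x)\,h + s\sqrt{h}\,Z}.  The slice density is
#' exact for this model family, so this integrator exists as an independent
#' brute-force check of the closed forms (its endpoint moments converge to
#' the slice-density moments as `step` shrinks), not as a production
#' simulator — use [sample_transition()] for that.
#'
#' @inheritParams sample_transition
#' @param step time step in months; must satisfy `0 < step < t1 - t0`.
#' @param n number of independent paths (endpoints are returned).
#' @return numeric vector of `n` path endpoints.
#' @export
euler_maruyama <- function(model, x0, t0, t1, site = NULL, step, n = 1L) {
  stopifnot(inherits(model, "sde_model"))
  if (step <= 0) stop("'step' must be > 0")
  if (t1 < t0) stop("time must not run backwards: t1 < t0")
  if (step >= t1 - t0) stop("'step' must be smaller than t1 - t0")
  th <- site_params(model, site)
  x <- rep_len(x0, n)
  t <- t0
  sqh <- sqrt(step)
  while (t < t1 - 1e-12) {
    h <- min(step, t1 - t)
    mu <- th[["a2"]] + th[["a3"]] * t + th[["a4"]] * t^2 + th[["a5"]] * t^3 +
      th[["a1"]] * x
    noise <- if (th[["s"]] > 0) th[["s"]] * sqrt(h) * stats::rnorm(n) else 0
    x <- x + mu * h + noise
    t <- t + h
  }
  x
}

#' Simulate one trajectory over a visit schedule
#'
#' Chains exact transitions ([sample_transition()]) over strictly increasing
#' visit ages.  The first value is drawn from a configurable initial
#' Gaussian (the SDE models transitions only, so the starting value must be
#' supplied or simulated), unless `x0` is given.
#'
#' @param model an [sde_model()].
#' @param ages strictly increasing visit ages (months).
#' @param site optional site label.
#' @param x0 optional fixed initial value; when `NULL`, drawn from
#'   `Normal(init_mean, init_sd^2)`.
#' @param init_mean,init_sd initial-distribution parameters (z-scores).
#' @return data.frame with columns `age_months`, `zwfl`.
#' @export
simulate_trajectory <- function(model, ages, site = NULL, x0 = NULL,
                                init_mean = 0, init_sd = 1) {
  if (length(ages) == 0L) stop("empty visit schedule")
  if (any(diff(ages) <= 0)) stop("visit ages must be strictly increasing")
  x <- numeric(length(ages))
  x[1L] <- if (is.null(x0)) stats::rnorm(1L, init_mean, init_sd) else x0
  if (length(ages) > 1L) {
    for (k in 2:length(ages)) {
      x[k] <- sample_transition(model, x[k - 1L], ages[k - 1L], ages[k], site)
    }
  }
  data.frame(age_months = ages, zwfl = x)
}

#' Design of a synthetic longitudinal cohort
#'
#' Describes the observation process of a birth-cohort anthropometry study:
#' a target schedule of monthly visits over ages 0-24 months, Gaussian visit
#' jitter truncated to the +/- 14-day visit window, independent per-visit
#' missingness (first visit always kept, so every child has an anchor), an
#' initial-value distribution per site, and child-level Gaussian random
#' effects on the model parameters named in the model's
#' `random_effect_names`.
#'
#' Defaults emulate the structure of the motivating two-site cohort:
#' schedule 0,1,...,24 months; jitter sd of 5 days; `p_visit_missing =
#' 0.03`, under which the expected share of children with at least 24 of 25
#' visits is `pbinom(1, 24, 0.03)`, about 0.84 — the completeness level
#' reported for such cohorts.
#'
#' @param n_children_per_site children per site.
#' @param sites character vector of site labels.
#' @param visit_ages target schedule in months.
#' @param age_jitter_sd jitter standard deviation, months (default 5 days).
#' @param p_visit_missing probability each non-anchor visit is missed.
#' @param random_effects_cov covariance matrix (or named diagonal vector) of
#'   the child-level random effects over the model's `random_effect_names`;
#'   `NULL` means no random effects.
#' @param init_mean,init_sd initial ZWfL distribution; either scalars or
#'   vectors named by site.
#' @param seed integer seed used by [simulate_cohort()]; `NULL` leaves the
#'   RNG stream untouched.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(n_children_per_site, sites = c("SiteA", "SiteB"),
                          visit_ages = 0:24,
                          age_jitter_sd = 5 / DAYS_PER_MONTH,
                          p_visit_missing = 0.03,
                          random_effects_cov = NULL,
                          init_mean = 0, init_sd = 1, seed = NULL) {
  if (p_visit_missing < 0 || p_visit_missing > 1)
    stop("'p_visit_missing' must be in [0, 1]")
  if (age_jitter_sd < 0) stop("'age_jitter_sd' must be >= 0")
  if (any(diff(visit_ages) <= 0))
    stop("'visit_ages' must be strictly increasing")
  if (!is.null(random_effects_cov)) {
    if (is.vector(random_effects_cov))
      random_effects_cov <- diag(random_effects_cov,
                                 nrow = length(random_effects_cov)) |>
        `dimnames<-`(list(names(random_effects_cov),
                          names(random_effects_cov)))
    if (!isSymmetric(unname(random_effects_cov)))
      stop("'random_effects_cov' must be symmetric")
    if (any(eigen(random_effects_cov, symmetric = TRUE,
                  only.values = TRUE)$values < -1e-10))
      stop("'random_effects_cov' must be positive semi-definite")
  }
  structure(list(n_children_per_site = as.integer(n_children_per_site),
                 sites = sites, visit_ages = visit_ages,
                 age_jitter_sd = age_jitter_sd,
                 p_visit_missing = p_visit_missing,
                 random_effects_cov = random_effects_cov,
                 init_mean = init_mean, init_sd = init_sd, seed = seed),
            class = "cohort_design")
}

site_scalar <- function(x, site) {
  if (!is.null(names(x)) && site %in% names(x)) x[[site]] else x[[1L]]
}

# truncated-normal jitter: reject outside the +/-14 day window, clamp as a
# last resort (the window is ~2.8 sd away at the default sd, so rejection
# essentially never recurs)
visit_jitter <- function(n, sd) {
  if (sd == 0 || n == 0L) return(numeric(n))
  j <- stats::rnorm(n, 0, sd)
  for (i in 1:50) {
    bad <- abs(j) > JITTER_CAP_MONTHS
    if (!any(bad)) break
    j[bad] <- stats::rnorm(sum(bad), 0, sd)
  }
  pmin(pmax(j, -JITTER_CAP_MONTHS), JITTER_CAP_MONTHS)
}

# apply a named random-effect / offset vector to a parameter vector;
# effects on s act on log(s)
apply_param_effects <- function(th, b) {
  for (p in names(b)) {
    if (p == "s") th[["s"]] <- th[["s"]] * exp(b[[p]])
    else th[[p]] <- th[[p]] + b[[p]]
  }
  th
}

#' Simulate a synthetic cohort
#'
#' Generates `n_children_per_site * length(sites)` trajectories under an
#' [sde_model()] and a [cohort_design()].  Per child: random effects are
#' drawn once from `Normal(0, random_effects_cov)` and held fixed; visit
#' ages are the schedule plus truncated Gaussian jitter (sorted); non-anchor
#' visits are dropped independently with probability `p_visit_missing`; the
#' initial value comes from the per-site initial Gaussian and subsequent
#' values from exact slice-density transitions under the child's own
#' parameters.
#'
#' @param model an [sde_model()]; its `random_effect_names` say which
#'   parameters the design's `random_effects_cov` perturbs.
#' @param design a [cohort_design()].
#' @return a `growth_cohort` data.frame with columns
#'   `child_id, site, age_months, zwfl`, sorted by child then age, carrying
#'   the per-child random effects in `attr(, "random_effects")`.
#' @export
simulate_cohort <- function(model, design) {
  stopifnot(inherits(model, "sde_model"), inherits(design, "cohort_design"))
  if (!is.null(design$seed)) set.seed(design$seed)
  re_names <- model$random_effect_names
  Sig <- design$random_effects_cov
  if (length(re_names) && !is.null(Sig)) {
    if (is.null(rownames(Sig))) dimnames(Sig) <- list(re_names, re_names)
    Sig <- Sig[re_names, re_names, drop = FALSE]
    # symmetric square root: exact also for singular (e.g. zero) covariances
    ev <- eigen(Sig, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(Sig)) %*%
      t(ev$vectors)
  } else {
    re_names <- character()
  }
  rows <- vector("list", design$n_children_per_site * length(design$sites))
  re_rows <- list()
  k <- 0L
  for (site in design$sites) {
    th_site <- site_params(model, site)
    for (i in seq_len(design$n_children_per_site)) {
      k <- k + 1L
      id <- sprintf("%s_%03d", site, i)
      b <- if (length(re_names)) {
        bv <- drop(t(L) %*% stats::rnorm(length(re_names)))
        names(bv) <- re_names
        bv
      } else NULL
      th <- if (is.null(b)) th_site else apply_param_effects(th_site, b)
      ages <- sort(design$visit_ages +
                     visit_jitter(length(design$visit_ages),
                                  design$age_jitter_sd))
      ages <- pmax(ages, 0)
      keep <- c(TRUE, stats::runif(length(ages) - 1L) >=
                  design$p_visit_missing)
      ages <- ages[keep]
      x <- numeric(length(ages))
      x[1L] <- stats::rnorm(1L, site_scalar(design$init_mean, site),
                            site_scalar(design$init_sd, site))
      if (length(ages) > 1L) {
        mo <- NULL
        for (j in 2:length(ages)) {
          mo <- slice_moments_theta(ages[j - 1L], ages[j], x[j - 1L], th)
          x[j] <- stats::rnorm(1L, mo$mean, sqrt(mo$var))
        }
      }
      rows[[k]] <- data.frame(child_id = id, site = site,
                              age_months = ages, zwfl = x)
      if (!is.null(b)) re_rows[[id]] <- b
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("growth_cohort", "data.frame")
  if (length(re_rows)) attr(out, "random_effects") <- re_rows
  out
}
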