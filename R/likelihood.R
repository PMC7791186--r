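# Transition-likelihood machinery.
#
# The log-likelihood of a trajectory X_0, ..., X_{N-1} observed at ages
# t_0 < ... < t_{N-1} is the sum of log slice densities over consecutive
# transitions; the first observation is conditioned on (treated as a
# constant), so it contributes no term.  Children are independent, so a
# cohort's log-likelihood is the sum over children.

# Flatten a cohort into transition vectors plus child/site bookkeeping.
build_transitions <- function(cohort) {
  cohort <- as.data.frame(cohort)
  req <- c("child_id", "site", "age_months", "zwfl")
  missing <- setdiff(req, names(cohort))
  if (length(missing))
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "))
  ord <- order(cohort$child_id, cohort$age_months)
  cohort <- cohort[ord, ]
  ids <- unique(cohort$child_id)
  child <- match(cohort$child_id, ids)
  n <- nrow(cohort)
  same <- child[-1L] == child[-n]
  if (any(same & diff(cohort$age_months) <= 0))
    stop("ages must be strictly increasing within each child")
  first_row <- match(seq_along(ids), child)
  counts <- tabulate(child)
  if (any(counts < 2L))
    stop("every trajectory needs >= 2 points for likelihood use (child ",
         ids[which(counts < 2L)[1L]], " has ", min(counts), ")")
  keep <- which(same)
  list(t0 = cohort$age_months[keep], t1 = cohort$age_months[keep + 1L],
       x0 = cohort$zwfl[keep], x1 = cohort$zwfl[keep + 1L],
       child = child[keep],
       children = ids,
       site_of_child = cohort$site[first_row],
       first_age = cohort$age_months[first_row],
       first_val = cohort$zwfl[first_row],
       n_children = length(ids), n_obs = n)
}

# negative log-likelihood of all transitions given an n_children x 6 matrix
# of natural parameters (columns a1..a5, s); returns either the total or the
# per-child vector
nll_transitions <- function(trans, P, per_child = FALSE) {
  ci <- trans$child
  mo <- slice_moments(trans$t0, trans$t1, trans$x0,
                      P[ci, 1L], P[ci, 2L], P[ci, 3L], P[ci, 4L], P[ci, 5L],
                      P[ci, 6L])
  ll <- stats::dnorm(trans$x1, mo$mean, sqrt(mo$var), log = TRUE)
  if (per_child) -drop(rowsum(ll, ci, reorder = TRUE)) else -sum(ll)
}

#' Negative log-likelihood of a single trajectory
#'
#' Sums the negative log slice densities over consecutive observed
#' transitions of one child; the first observation is conditioned on as a
#' constant and contributes no term.  Irregular or missing visits need no
#' special handling: each transition spans whatever age gap separates the
#' two observations.
#'
#' @param model an [sde_model()] supplying the parameters.
#' @param trajectory data.frame with columns `age_months` and `zwfl`
#'   (strictly increasing ages, >= 2 rows); a `site` column is used when
#'   `site` is not given.
#' @param site optional site label.
#' @return the negative log-likelihood (a single number; `+Inf` with a
#'   warning if a zero-variance transition disagrees with the observed
#'   value).
#' @examples
#' ou <- ou_model(alpha = 1, beta = 0, sigma = 1)
#' tr <- data.frame(age_months = c(0, 1), zwfl = c(0, 0.2))
#' trajectory_negloglik(ou, tr)  # ~ 0.5460
#' @export
trajectory_negloglik <- function(model, trajectory, site = NULL) {
  stopifnot(inherits(model, "sde_model"))
  trajectory <- as.data.frame(trajectory)
  if (nrow(trajectory) < 2L) stop("trajectory needs >= 2 points")
  if (any(diff(trajectory$age_months) <= 0))
    stop("ages must be strictly increasing")
  if (is.null(site) && "site" %in% names(trajectory))
    site <- trajectory$site[1L]
  th <- site_params(model, site)
  n <- nrow(trajectory)
  mo <- slice_moments_theta(trajectory$age_months[-n],
                            trajectory$age_months[-1L],
                            trajectory$zwfl[-n], th)
  x1 <- trajectory$zwfl[-1L]
  if (any(mo$var == 0)) {
    deg <- mo$var == 0
    if (any(abs(x1[deg] - mo$mean[deg]) > 0)) {
      warning("zero-variance transition disagrees with observed value; ",
              "negative log-likelihood is +Inf")
      return(Inf)
    }
  }
  -sum(stats::dnorm(x1, mo$mean, sqrt(mo$var), log = TRUE)[mo$var > 0])
}

#' Negative log-likelihood of a cohort
#'
#' Sum of [trajectory_negloglik()] over the independent children of a
#' cohort, evaluated with one vectorised pass over all transitions.
#'
#' @param model an [sde_model()].
#' @param cohort a `growth_cohort` data.frame
#'   (`child_id, site, age_months, zwfl`).
#' @return total negative log-likelihood.
#' @export
cohort_negloglik <- function(model, cohort) {
  stopifnot(inherits(model, "sde_model"))
  trans <- build_transitions(cohort)
  P <- t(vapply(trans$site_of_child,
                function(st) site_params(model, st), numeric(6L)))
  nll_transitions(trans, P)
}
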