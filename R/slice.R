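# Closed-form Gaussian slice densities for the linear-drift family.
#
# For dX = (p(t) + a1*X) dt + s dW with p(t) = a2 + a3 t + a4 t^2 + a5 t^3,
# the integrating factor exp(-a1 t) gives, for t1 >= t0 and Delta = t1 - t0,
#
#   X_{t1} | X_{t0} = x0  ~  Normal(m, v),
#   m = exp(a1 Delta) x0 + int_{t0}^{t1} exp(a1 (t1 - u)) p(u) du
#   v = s^2 (exp(2 a1 Delta) - 1) / (2 a1)      (-> s^2 Delta as a1 -> 0).
#
# Expanding p about t0 (Taylor coefficients c_j = p^(j)(t0) / j!) and
# substituting u = t0 + v turns the drift integral into
# sum_j c_j j! Delta^(j+1) phi_{j+1}(a1 Delta) and the variance into
# s^2 Delta phi_1(2 a1 Delta), which is exact for every a1 including a1 = 0
# and free of the cancellation the raw exponential expressions suffer near
# a1 = 0.

# Vectorised moment kernel: all arguments recycled to a common length.
# This is the computational hot path shared by simulation, likelihood and
# prediction; a1..a5, s may vary per element (per-child parameters).
slice_moments <- function(t0, t1, x0, a1, a2, a3, a4, a5, s) {
  n <- max(length(t0), length(t1), length(x0), length(a1), length(a2),
           length(a3), length(a4), length(a5), length(s))
  t0 <- rep_len(t0, n); t1 <- rep_len(t1, n); x0 <- rep_len(x0, n)
  a1 <- rep_len(a1, n); a2 <- rep_len(a2, n); a3 <- rep_len(a3, n)
  a4 <- rep_len(a4, n); a5 <- rep_len(a5, n); s <- rep_len(s, n)
  dt <- t1 - t0
  z <- a1 * dt
  c0 <- a2 + t0 * (a3 + t0 * (a4 + t0 * a5))
  c1 <- a3 + t0 * (2 * a4 + 3 * t0 * a5)
  c2 <- a4 + 3 * a5 * t0
  c3 <- a5
  # only the phi orders the drift polynomial actually excites
  kmax <- if (any(c3 != 0)) 4L else if (any(c2 != 0)) 3L
          else if (any(c1 != 0)) 2L else 1L
  ph <- phi_funs(z, kmax)
  acc <- if (kmax >= 4L) dt * 6 * c3 * ph[, 4L] else 0
  if (kmax >= 3L) acc <- dt * (2 * c2 * ph[, 3L] + acc)
  if (kmax >= 2L) acc <- dt * (c1 * ph[, 2L] + acc)
  mean <- exp(z) * x0 + dt * (c0 * ph[, 1L] + acc)
  var <- s^2 * dt * phi_funs(2 * z, 1L)[, 1L]
  var[dt == 0] <- 0
  list(mean = mean, var = var)
}

slice_moments_theta <- function(t0, t1, x0, theta) {
  slice_moments(t0, t1, x0, theta[["a1"]], theta[["a2"]], theta[["a3"]],
                theta[["a4"]], theta[["a5"]], theta[["s"]])
}

#' Transition (slice) density of a linear SDE
#'
#' The exact conditional law of the process at age `t1` given state `x0` at
#' age `t0`: Gaussian with mean
#' \deqn{m = e^{a_1\Delta} x_0 + \int_{t_0}^{t_1} e^{a_1(t_1-u)} p(u)\,du}
#' and variance \eqn{s^2 (e^{2a_1\Delta} - 1)/(2a_1)} (limits
#' \eqn{x_0 + \int p} and \eqn{s^2\Delta} when there is no mean reversion).
#' For an OU model this reduces to mean
#' \eqn{e^{-\alpha\Delta}(x_0-\beta)+\beta} and variance
#' \eqn{\sigma^2(1-e^{-2\alpha\Delta})/(2\alpha)}.
#'
#' @param model an [sde_model()].
#' @param x0 state at `t0` (z-score).
#' @param t0,t1 ages in months, `t1 >= t0`.
#' @param site optional site label.
#' @return object of class `slice_density`: list with elements `mean`
#'   (z-score) and `variance` (z-score^2, 0 iff `t1 == t0`).
#' @examples
#' ou <- ou_model(alpha = 2, beta = 0, sigma = 1)
#' slice_density(ou, x0 = 1, t0 = 0, t1 = 0.3)  # mean ~ 0.5488, var ~ 0.1747
#' @export
slice_density <- function(model, x0, t0, t1, site = NULL) {
  stopifnot(inherits(model, "sde_model"))
  if (t1 < t0) stop("time must not run backwards: t1 < t0")
  if (!is.finite(x0) || !is.finite(t0) || !is.finite(t1))
    stop("x0, t0, t1 must be finite")
  th <- site_params(model, site)
  mo <- slice_moments_theta(t0, t1, x0, th)
  structure(list(mean = mo$mean, variance = mo$var), class = "slice_density")
}

#' @export
print.slice_density <- function(x, ...) {
  cat(sprintf("slice density: Normal(mean = %.6g, variance = %.6g)\n",
              x$mean, x$variance))
  invisible(x)
}

#' Covariance function of the Ornstein-Uhlenbeck process
#'
#' For an OU process started as a constant at age `t0`, the covariance
#' between its values at ages `s_time` and `t_time` is
#' \deqn{\mathrm{Cov}(X_s, X_t) =
#'   \frac{e^{-(s+t)\alpha}(e^{2\alpha\min(s,t)} - e^{2 t_0 \alpha})
#'   \sigma^2}{2\alpha}.}
#' Symmetric in its two time arguments and zero when either equals `t0`.
#'
#' @param model an OU [sde_model()] (e.g. from [ou_model()]); other models
#'   are an error, the formula is OU-specific.
#' @param t0 starting age (months), `t0 <= min(s_time, t_time)`.
#' @param s_time,t_time the two ages (months).
#' @param site optional site label.
#' @return covariance in z-score^2 units.
#' @export
ou_covariance <- function(model, t0, s_time, t_time, site = NULL) {
  stopifnot(inherits(model, "sde_model"))
  if (!is_ou(model))
    stop("ou_covariance() is specific to the OU model ",
         "(drift_order 0 with mean reversion, a1 < 0)")
  if (t0 > min(s_time, t_time))
    stop("t0 must not exceed min(s_time, t_time)")
  th <- site_params(model, site)
  alpha <- -th[["a1"]]
  sigma <- th[["s"]]
  exp(-(s_time + t_time) * alpha) *
    (-exp(2 * t0 * alpha) + exp(2 * alpha * pmin(s_time, t_time))) *
    sigma^2 / (2 * alpha)
}
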