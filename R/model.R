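#' Specify a linear-drift stochastic differential equation model
#'
#' Defines a member of the linear-SDE family
#' \deqn{dX_t = (p(t) + a_1 X_t)\,dt + s\,dW_t,}
#' where \eqn{p(t) = a_2 + a_3 t + a_4 t^2 + a_5 t^3} is a polynomial in age
#' (months) of order `drift_order`, \eqn{a_1 X_t} is an optional
#' mean-reversion term, and \eqn{s > 0} is a constant diffusion.  For this
#' family the transition ("slice") density of \eqn{X_{t_1}} given
#' \eqn{(X_{t_0}, t_0)} is Gaussian in closed form; see [slice_density()].
#'
#' The Ornstein-Uhlenbeck (OU) process \eqn{dX = \alpha(\beta - X)dt +
#' \sigma dW} is the special case `drift_order = 0`, `mean_reversion = TRUE`
#' with \eqn{a_1 = -\alpha}, \eqn{a_2 = \alpha\beta}; use [ou_model()] for
#' that parameterisation directly.
#'
#' Site effects enter the drift parameters additively and the diffusion on
#' the log scale (so that \eqn{s > 0} is preserved for every site).
#' `site_offsets` is a named list mapping a parameter name (`"a1"` ...
#' `"a5"`, `"s"`) to a named numeric vector of per-site offsets; every site
#' label the model should accept must appear (use an explicit 0 for the
#' reference site), or pass `sites` to fix the label set.
#'
#' @param drift_order integer 0-3, order of the age polynomial \eqn{p(t)}.
#' @param mean_reversion logical; include the \eqn{a_1 X} term?
#' @param params named numeric vector with entries among
#'   `a1, a2, a3, a4, a5, s`; entries not implied by `drift_order` /
#'   `mean_reversion` must be absent. `s` is required and positive.
#' @param site_offsets named list of per-site additive offsets (see Details).
#' @param sites optional character vector of valid site labels; inferred
#'   from `site_offsets` when omitted.
#' @param random_effect_names character subset of parameter names that carry
#'   child-level random effects (used by [simulate_cohort()] and
#'   [fit_mixed_sde()]; effects on `s` act on `log(s)`).
#' @return an object of class `sde_model`.
#' @seealso [ou_model()], [drift()], [slice_density()], [simulate_cohort()]
#' @examples
#' m <- sde_model(drift_order = 1, mean_reversion = TRUE,
#'                params = c(a1 = -0.8, a2 = -0.2, a3 = 0.01, s = 0.5))
#' drift(m, t = 6, x = -1)
#' @export
sde_model <- function(drift_order, mean_reversion, params,
                      site_offsets = list(), sites = NULL,
                      random_effect_names = character()) {
  drift_order <- as.integer(drift_order)
  if (drift_order < 0L || drift_order > 3L)
    stop("'drift_order' must be an integer in 0..3")
  allowed <- c(if (mean_reversion) "a1",
               paste0("a", 2:(2 + drift_order)), "s")
  if (is.null(names(params)) || any(names(params) == ""))
    stop("'params' must be a fully named numeric vector")
  extra <- setdiff(names(params), allowed)
  if (length(extra))
    stop("unused parameter(s) for this model: ", paste(extra, collapse = ", "))
  missing <- setdiff(allowed, names(params))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  if (!is.finite(params[["s"]]) || params[["s"]] <= 0)
    stop("'s' (diffusion) must be finite and > 0")
  if (!mean_reversion && "a1" %in% names(params) && params[["a1"]] != 0)
    stop("a1 must be absent (0) when mean_reversion is FALSE")

  if (length(site_offsets)) {
    bad <- setdiff(names(site_offsets), c("a1", "a2", "a3", "a4", "a5", "s"))
    if (length(bad))
      stop("site_offsets name unknown parameter(s): ",
           paste(bad, collapse = ", "))
    offset_sites <- sort(unique(unlist(lapply(site_offsets, names))))
    if (is.null(sites)) sites <- offset_sites
    # offsets on s act on log(s): s stays positive by construction, but check
    for (lab in sites) {
      s_eff <- params[["s"]] * exp(offset_for(site_offsets, "s", lab))
      if (!is.finite(s_eff) || s_eff <= 0)
        stop("diffusion is not positive for site '", lab, "'")
    }
  }
  bad_re <- setdiff(random_effect_names, allowed)
  if (length(bad_re))
    stop("random_effect_names not in model parameters: ",
         paste(bad_re, collapse = ", "))

  structure(
    list(drift_order = drift_order,
         mean_reversion = isTRUE(mean_reversion),
         params = params[allowed],
         site_offsets = site_offsets,
         sites = sites,
         random_effect_names = random_effect_names),
    class = "sde_model")
}

offset_for <- function(site_offsets, par, site) {
  v <- site_offsets[[par]]
  if (is.null(v) || is.null(site) || !(site %in% names(v))) 0 else v[[site]]
}

#' Ornstein-Uhlenbeck model in its natural parameterisation
#'
#' Convenience constructor for the mean-reverting process
#' \eqn{dX = \alpha(\beta - X)dt + \sigma dW} with speed of reversion
#' \eqn{\alpha > 0}, long-term mean \eqn{\beta}, and diffusion
#' \eqn{\sigma > 0}.  Internally this is [sde_model()] with `drift_order =
#' 0`, `mean_reversion = TRUE`, \eqn{a_1 = -\alpha}, \eqn{a_2 = \alpha\beta}.
#'
#' @param alpha speed of mean reversion, per month; must be > 0.
#' @param beta long-term mean (z-score units).
#' @param sigma diffusion (z-score per sqrt-month); must be > 0.
#' @param ... further arguments passed to [sde_model()] (`site_offsets`,
#'   `random_effect_names`, ...).
#' @return an `sde_model` that also records `(alpha, beta, sigma)`.
#' @examples
#' ou <- ou_model(alpha = 1, beta = -0.5, sigma = 0.7)
#' slice_density(ou, x0 = 1, t0 = 0, t1 = 2)
#' @export
ou_model <- function(alpha, beta, sigma, ...) {
  if (alpha <= 0) stop("'alpha' must be > 0")
  m <- sde_model(drift_order = 0L, mean_reversion = TRUE,
                 params = c(a1 = -alpha, a2 = alpha * beta, s = sigma), ...)
  m$ou <- c(alpha = alpha, beta = beta, sigma = sigma)
  m
}

is_ou <- function(model) {
  model$drift_order == 0L && model$mean_reversion &&
    model$params[["a1"]] < 0
}

# Full (a1..a5, s) vector for one site, offsets applied.  Unknown site
# labels are an error so that typos never silently get reference parameters.
site_params <- function(model, site = NULL) {
  if (!is.null(model$sites) && !is.null(site) && !(site %in% model$sites))
    stop("unknown site label '", site, "'")
  th <- c(a1 = 0, a2 = 0, a3 = 0, a4 = 0, a5 = 0, s = 0)
  th[names(model$params)] <- model$params
  if (length(model$site_offsets) && !is.null(site)) {
    for (par in names(model$site_offsets)) {
      off <- offset_for(model$site_offsets, par, site)
      if (par == "s") th[["s"]] <- th[["s"]] * exp(off)
      else th[[par]] <- th[[par]] + off
    }
  }
  th
}

#' Drift of an SDE model
#'
#' Evaluates the deterministic rate-of-change component
#' \eqn{\mu(t, x) = p(t) + a_1 x} (z-score per month) at age `t` and state
#' `x`, with per-site offsets applied.  For an OU model this equals
#' \eqn{\alpha(\beta - x)}.
#'
#' @param model an [sde_model()].
#' @param t age in months (vectorised), must be >= 0.
#' @param x state, z-score units (vectorised).
#' @param site optional site label; required to resolve site offsets.
#' @return drift rate(s), z-score/month.
#' @export
drift <- function(model, t, x, site = NULL) {
  stopifnot(inherits(model, "sde_model"))
  if (any(t < 0)) stop("age 't' must be >= 0")
  th <- site_params(model, site)
  th[["a2"]] + th[["a3"]] * t + th[["a4"]] * t^2 + th[["a5"]] * t^3 +
    th[["a1"]] * x
}

#' @export
print.sde_model <- function(x, ...) {
  fam <- if (is_ou(x) && !is.null(x$ou)) "Ornstein-Uhlenbeck"
         else sprintf("linear SDE (drift order %d%s)", x$drift_order,
                      if (x$mean_reversion) ", mean-reverting" else "")
  cat("SDE model:", fam, "\n")
  cat("  dX = (p(t)", if (x$mean_reversion) "+ a1*X" else "",
      ") dt + s dW\n")
  cat("  parameters:\n")
  print(round(x$params, 6))
  if (!is.null(x$ou))
    cat(sprintf("  OU form: alpha=%.4g beta=%.4g sigma=%.4g\n",
                x$ou[["alpha"]], x$ou[["beta"]], x$ou[["sigma"]]))
  if (length(x$site_offsets)) {
    cat("  site offsets (s on log scale):\n")
    for (p in names(x$site_offsets)) {
      cat("   ", p, ": ",
          paste(sprintf("%s=%+.4g", names(x$site_offsets[[p]]),
                        x$site_offsets[[p]]), collapse = "  "), "\n", sep = "")
    }
  }
  if (length(x$random_effect_names))
    cat("  random effects on:", paste(x$random_effect_names, collapse = ", "),
        "\n")
  invisible(x)
}

#' Serialise / restore a model specification
#'
#' `model_to_config()` converts an [sde_model()] to a plain list with keys
#' `drift_order`, `mean_reversion`, `params`, `site_offsets`,
#' `random_effect_names`; `model_from_config()` inverts it.
#' `write_model_config()` / `read_model_config()` do the same through a YAML
#' file, losslessly.
#'
#' @param model an `sde_model`.
#' @param config a list as produced by `model_to_config()`.
#' @param path file path of the YAML configuration.
#' @return `model_to_config()` a list; `model_from_config()` and
#'   `read_model_config()` an `sde_model`; `write_model_config()` the path,
#'   invisibly.
#' @export
model_to_config <- function(model) {
  stopifnot(inherits(model, "sde_model"))
  list(drift_order = model$drift_order,
       mean_reversion = model$mean_reversion,
       params = as.list(model$params),
       site_offsets = lapply(model$site_offsets, as.list),
       random_effect_names = as.list(model$random_effect_names))
}

#' @rdname model_to_config
#' @export
model_from_config <- function(config) {
  req <- c("drift_order", "mean_reversion", "params")
  missing <- setdiff(req, names(config))
  if (length(missing))
    stop("model config missing key(s): ", paste(missing, collapse = ", "))
  sde_model(
    drift_order = config$drift_order,
    mean_reversion = config$mean_reversion,
    params = unlist(config$params),
    site_offsets = lapply(config$site_offsets %||% list(), unlist),
    random_effect_names = as.character(unlist(
      config$random_effect_names %||% character())))
}

#' @rdname model_to_config
#' @export
write_model_config <- function(model, path) {
  yaml::write_yaml(model_to_config(model), path)
  invisible(path)
}

#' @rdname model_to_config
#' @export
read_model_config <- function(path) {
  model_from_config(yaml::read_yaml(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
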