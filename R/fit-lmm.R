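# Linear mixed-model baseline: polynomial-in-age fixed effects with
# optional site interactions, unstructured (or diagonal) random effects on
# the age terms, and AR(1) or independent within-child errors.  The model
# class is standard, so the engine is nlme (lme / gls / lm, all by maximum
# likelihood); this module owns the specification surface, design checks,
# and AIC/BIC comparability with the SDE fits.

#' Specify a linear mixed model for growth trajectories
#'
#' @param poly_order order of the age polynomial (<= 4).
#' @param site_interactions character vector of site terms to include, e.g.
#'   `c("site", "age2:site")`; `"ageK:site"` crosses the K-th age power
#'   with site.
#' @param random_terms subset of `c("intercept", "age1", ..., "age4")`
#'   carrying child-level random effects; empty for none.
#' @param re_cov `"unstructured"` or `"diagonal"` random-effects covariance.
#' @param error_cov `"AR1"` (first-order autoregressive within-child errors,
#'   in visit order) or `"independent"`.
#' @return an object of class `lmm_spec`.
#' @export
lmm_spec <- function(poly_order, site_interactions = character(),
                     random_terms = c("intercept", "age1"),
                     re_cov = c("unstructured", "diagonal"),
                     error_cov = c("AR1", "independent")) {
  poly_order <- as.integer(poly_order)
  if (poly_order < 0L || poly_order > 4L)
    stop("'poly_order' must be an integer in 0..4")
  re_cov <- match.arg(re_cov)
  error_cov <- match.arg(error_cov)
  ok_re <- c("intercept", paste0("age", seq_len(max(poly_order, 1L))))
  bad <- setdiff(random_terms, ok_re)
  if (length(bad))
    stop("random_terms outside the age polynomial: ",
         paste(bad, collapse = ", "))
  structure(list(poly_order = poly_order,
                 site_interactions = site_interactions,
                 random_terms = random_terms,
                 re_cov = re_cov, error_cov = error_cov,
                 dropped = character()),
            class = "lmm_spec")
}

lmm_fixed_terms <- function(spec) {
  terms <- character()
  if (spec$poly_order >= 1L) terms <- paste0("age", seq_len(spec$poly_order))
  terms <- c(terms, spec$site_interactions)
  setdiff(terms, spec$dropped)
}

lmm_data <- function(cohort) {
  df <- as.data.frame(cohort)
  df <- df[order(df$child_id, df$age_months), ]
  for (k in 1:4) df[[paste0("age", k)]] <- df$age_months^k
  df$site <- factor(df$site)
  df$child_id <- factor(df$child_id)
  df$visit_idx <- stats::ave(seq_len(nrow(df)), df$child_id,
                             FUN = seq_along)
  df
}

#' Fit the linear mixed-model baseline
#'
#' Gaussian marginal likelihood with per-child covariance
#' \eqn{Z_i \Sigma_b Z_i^\top + \sigma^2 R_i}, where \eqn{R_i} is AR(1) in
#' visit order (or the identity), maximised by ML via `nlme`.  AIC/BIC are
#' directly comparable with SDE fits on the identical cohort (same
#' `n_obs`, same counting of fixed + variance/covariance parameters).
#'
#' @param spec an [lmm_spec()].
#' @param cohort a `growth_cohort` data.frame.
#' @param options list: `fix_ar1` (fix the AR(1) correlation at a value
#'   instead of estimating it), `control` (passed to [nlme::lmeControl()]).
#' @return a `growth_fit`; `details$engine` holds the underlying
#'   `lme`/`gls`/`lm` object.
#' @export
fit_lmm <- function(spec, cohort, options = list()) {
  stopifnot(inherits(spec, "lmm_spec"))
  df <- lmm_data(cohort)
  fterms <- lmm_fixed_terms(spec)
  if (any(grepl("site", fterms)) && nlevels(df$site) < 2L)
    stop("site terms requested but the cohort has a single site")
  fixed_rhs <- if (length(fterms)) paste(fterms, collapse = " + ") else "1"
  fixed <- stats::as.formula(paste("zwfl ~", fixed_rhs))
  X <- stats::model.matrix(fixed, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    collinear <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular fixed-effects design; collinear term(s): ",
         paste(collinear, collapse = ", "))
  }
  corr <- if (spec$error_cov == "AR1") {
    if (!is.null(options$fix_ar1))
      nlme::corAR1(value = options$fix_ar1, form = ~ visit_idx | child_id,
                   fixed = TRUE)
    else nlme::corAR1(form = ~ visit_idx | child_id)
  } else NULL

  has_re <- length(spec$random_terms) > 0L
  engine <- if (has_re) {
    re_terms <- sub("^intercept$", "1", spec$random_terms)
    if (!("1" %in% re_terms)) re_terms <- c("-1", re_terms)
    re_rhs <- paste(re_terms, collapse = " + ")
    pd_fun <- if (spec$re_cov == "unstructured") nlme::pdSymm else nlme::pdDiag
    random <- pd_fun(stats::as.formula(paste("~", re_rhs)))
    ctrl <- do.call(nlme::lmeControl,
                    options$control %||%
                      list(maxIter = 200, msMaxIter = 200, niterEM = 50,
                           opt = "optim", returnObject = TRUE))
    nlme::lme(fixed, data = df, random = list(child_id = random),
              correlation = corr, method = "ML", control = ctrl)
  } else if (!is.null(corr)) {
    nlme::gls(fixed, data = df, correlation = corr, method = "ML")
  } else {
    stats::lm(fixed, data = df)
  }

  ll <- stats::logLik(engine)
  k <- attr(ll, "df")
  if (inherits(engine, "lme")) {
    tt <- summary(engine)$tTable
    est <- tt[, "Value"]
    se <- tt[, "Std.Error"]
    pval <- tt[, "p-value"]
    re_cov_hat <- tryCatch(unclass(nlme::getVarCov(engine)),
                           error = function(e) NULL)
  } else if (inherits(engine, "gls")) {
    tt <- summary(engine)$tTable
    est <- tt[, "Value"]
    se <- tt[, "Std.Error"]
    pval <- tt[, "p-value"]
    re_cov_hat <- NULL
  } else {
    sm <- summary(engine)$coefficients
    est <- sm[, 1L]
    se <- sm[, 2L]
    pval <- sm[, 4L]
    re_cov_hat <- NULL
  }
  fit <- new_growth_fit("LMM", est, se, as.numeric(ll), n_params = k,
                        n_obs = nrow(df), converged = TRUE,
                        random_effects_cov_hat = re_cov_hat,
                        details = list(engine = engine, p_values = pval,
                                       spec = spec))
  fit
}
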