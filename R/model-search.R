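# AIC/BIC-guided model search with p-value trimming: enumerate candidate
# formulations (polynomial order up to cubic for the SDE drift, up to
# quartic for the LMM; candidate random-effect sets and covariance
# structures), then iteratively drop the weakest fixed term while its Wald
# p-value exceeds the cut-off (default 0.1).  All fits are returned, ranked
# by AIC; candidates that fail to fit are recorded, never fatal.

sde_template <- function(order, mean_reversion) {
  params <- c(if (mean_reversion) c(a1 = -0.5),
              stats::setNames(rep(0.1, order + 1L),
                              paste0("a", 2:(2 + order))),
              c(s = 1))
  sde_model(order, mean_reversion, params)
}

trim_sde <- function(template, cohort, parameterization, re, p_cut,
                     options) {
  dropped <- character()
  repeat {
    options$dropped <- dropped
    fit <- if (is.null(re)) {
      fit_mle(template, cohort, parameterization, options)
    } else {
      fit_mixed_sde(template, cohort, re_names = re$re_names,
                    re_cov_structure = re$re_cov %||% "diagonal",
                    parameterization = parameterization, options = options)
    }
    wt <- wald_table(fit)
    droppable <- wt[wt$term %in% c("a1", "a2", "a3", "a4", "a5"), ]
    droppable <- droppable[is.finite(droppable$p_value), ]
    if (nrow(droppable) <= 1L) break
    worst <- droppable[which.max(droppable$p_value), ]
    if (worst$p_value <= p_cut) break
    dropped <- c(dropped, worst$term)
  }
  fit$details$dropped <- dropped
  fit
}

trim_lmm <- function(spec, cohort, p_cut, options) {
  repeat {
    fit <- fit_lmm(spec, cohort, options)
    pv <- fit$details$p_values
    terms <- names(fit$estimates)
    droppable_labels <- lmm_fixed_terms(fit$details$spec)
    # map coefficient names back to specification term labels
    cand <- data.frame(term = terms, p = pv, stringsAsFactors = FALSE)
    cand <- cand[cand$term != "(Intercept)" & is.finite(cand$p), ]
    if (!nrow(cand)) break
    worst <- cand[which.max(cand$p), ]
    if (worst$p <= p_cut) break
    lab <- term_label_for_coef(worst$term, droppable_labels)
    if (is.null(lab)) break
    spec$dropped <- c(spec$dropped, lab)
    if (!length(lmm_fixed_terms(spec))) break
  }
  fit
}

term_label_for_coef <- function(coef_name, labels) {
  for (lab in labels) {
    base <- sub(":site$", "", lab)
    pat <- if (grepl(":site$", lab)) paste0("^", base, ":site")
           else if (lab == "site") "^site"
           else paste0("^", lab, "$")
    if (grepl(pat, coef_name)) return(lab)
  }
  NULL
}

#' Search over candidate model formulations
#'
#' Enumerates a family of candidate models, fits each, applies iterative
#' Wald p-value trimming (terms are only ever removed when p > `p_cut`),
#' and returns all successful fits ranked by AIC (BIC reported alongside).
#'
#' For `family = "sde"` the candidates are drift polynomial orders
#' `rules$orders` (default 0:3) crossed with `rules$mean_reversion`
#' (default TRUE) and the random-effect configurations in `rules$re_sets`
#' (default: fixed effects only).  For `family = "lmm"` they are polynomial
#' orders `rules$orders` (default 1:4) with the random terms / covariance /
#' error structure in `rules`.
#'
#' @param cohort a `growth_cohort` data.frame.
#' @param family `"sde"` or `"lmm"`.
#' @param rules list of search rules: `orders`, `p_cut` (default 0.1),
#'   `mean_reversion`, `re_sets` (list; each `NULL` for fixed-only or
#'   `list(re_names=, re_cov=)`), `parameterization`, `site_interactions`,
#'   `random_terms`, `re_cov`, `error_cov`, `options` (passed to the
#'   fitters).
#' @return object of class `model_search`: list with `fits` (ranked),
#'   `table` (candidate, AIC, BIC, n_params, converged) and `failures`.
#' @export
model_search <- function(cohort, family = c("sde", "lmm"), rules = list()) {
  family <- match.arg(family)
  p_cut <- rules$p_cut %||% 0.1
  options <- rules$options %||% list()
  fits <- list()
  labels <- character()
  failures <- list()

  if (family == "sde") {
    orders <- rules$orders %||% 0:3
    mrs <- rules$mean_reversion %||% TRUE
    re_sets <- rules$re_sets %||% list(NULL)
    parameterization <- rules$parameterization %||% "natural"
    for (ord in orders) for (mr in mrs) for (ri in seq_along(re_sets)) {
      re <- re_sets[[ri]]
      lab <- sprintf("sde order=%d mr=%s%s", ord, mr,
                     if (is.null(re)) "" else
                       paste0(" re={", paste(re$re_names, collapse = ","),
                              "}"))
      res <- tryCatch(
        trim_sde(sde_template(ord, mr), cohort, parameterization, re,
                 p_cut, options),
        error = function(e) e)
      if (inherits(res, "error")) failures[[lab]] <- conditionMessage(res)
      else { fits <- c(fits, list(res)); labels <- c(labels, lab) }
    }
  } else {
    orders <- rules$orders %||% 1:4
    for (ord in orders) {
      spec <- lmm_spec(ord,
                       site_interactions = rules$site_interactions %||%
                         character(),
                       random_terms = intersect(
                         rules$random_terms %||% c("intercept", "age1"),
                         c("intercept", paste0("age", seq_len(max(ord, 1L))))),
                       re_cov = rules$re_cov %||% "unstructured",
                       error_cov = rules$error_cov %||% "AR1")
      lab <- sprintf("lmm order=%d", ord)
      res <- tryCatch(trim_lmm(spec, cohort, p_cut, options),
                      error = function(e) e)
      if (inherits(res, "error")) failures[[lab]] <- conditionMessage(res)
      else { fits <- c(fits, list(res)); labels <- c(labels, lab) }
    }
  }
  if (length(fits)) {
    aics <- vapply(fits, function(f) f$aic, numeric(1L))
    ord <- order(aics)
    fits <- fits[ord]
    labels <- labels[ord]
    tab <- data.frame(candidate = labels,
                      aic = vapply(fits, function(f) f$aic, numeric(1L)),
                      bic = vapply(fits, function(f) f$bic, numeric(1L)),
                      n_params = vapply(fits, function(f) f$n_params,
                                        numeric(1L)),
                      converged = vapply(fits, function(f)
                        isTRUE(f$converged), logical(1L)),
                      row.names = NULL)
  } else {
    tab <- data.frame(candidate = character(), aic = numeric(),
                      bic = numeric(), n_params = numeric(),
                      converged = logical())
  }
  structure(list(fits = fits, table = tab, failures = failures),
            class = "model_search")
}

#' @export
print.model_search <- function(x, ...) {
  cat("model search:", nrow(x$table), "candidate(s) fitted",
      if (length(x$failures)) paste0(", ", length(x$failures), " failed"),
      "\n")
  print(x$table)
  invisible(x)
}
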