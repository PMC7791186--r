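# Cohort ingestion/validation, summaries, and the pipeline runner.

#' Read and validate a cohort CSV
#'
#' Expects a long-format file with header
#' `child_id,site,age_months,zwfl` (comma-separated, `.` decimal, UTF-8;
#' leading `#` comment lines are skipped).  Validates: numeric,
#' non-negative, finite ages; finite z-scores; no duplicated
#' `(child_id, age_months)` visit; each child observed at a single site.
#' Violations are reported with the offending data row numbers.
#'
#' @param path CSV file path.
#' @return a `growth_cohort` data.frame sorted by child then age.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("child_id", "site", "age_months", "zwfl")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("cohort file missing column(s): ", paste(missing, collapse = ", "))
  df$child_id <- as.character(df$child_id)
  df$site <- as.character(df$site)
  if (!is.numeric(df$age_months))
    stop("column 'age_months' is not numeric")
  if (!is.numeric(df$zwfl))
    stop("column 'zwfl' is not numeric")
  as_growth_cohort(df[req])
}

#' Validate a data.frame as a growth cohort
#'
#' @param df data.frame with columns `child_id, site, age_months, zwfl`.
#' @return a validated, sorted `growth_cohort`.
#' @export
as_growth_cohort <- function(df) {
  df <- as.data.frame(df)
  bad <- which(!is.finite(df$age_months) | df$age_months < 0)
  if (length(bad))
    stop("invalid age_months (must be finite and >= 0) at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  bad <- which(!is.finite(df$zwfl))
  if (length(bad))
    stop("non-finite zwfl at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  dup <- which(duplicated(df[c("child_id", "age_months")]))
  if (length(dup))
    stop("duplicated (child_id, age_months) visit at row(s): ",
         paste(utils::head(dup, 10L), collapse = ", "))
  multi <- tapply(df$site, df$child_id, function(s) length(unique(s)))
  if (any(multi > 1L))
    stop("child(ren) observed at multiple sites: ",
         paste(utils::head(names(multi)[multi > 1L], 5L), collapse = ", "))
  df <- df[order(df$child_id, df$age_months), ]
  rownames(df) <- NULL
  class(df) <- c("growth_cohort", "data.frame")
  df
}

#' Write a cohort CSV
#'
#' Long format with header `child_id,site,age_months,zwfl`, full
#' floating-point precision (a write/read round-trip is lossless), and an
#' optional `#` provenance comment line.
#'
#' @param cohort a `growth_cohort`.
#' @param path output path.
#' @param provenance optional character line (seed, config hash, ...).
#' @return the path, invisibly.
#' @export
write_cohort <- function(cohort, path, provenance = NULL) {
  cohort <- as.data.frame(cohort)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(if (!is.null(provenance)) paste0("# ", provenance),
               "child_id,site,age_months,zwfl"), con)
  writeLines(paste(cohort$child_id, cohort$site,
                   num17(cohort$age_months), num17(cohort$zwfl), sep = ","),
             con)
  invisible(path)
}

#' Summarise a cohort by site
#'
#' Per site: number of children, the visit-count distribution, the share of
#' children with at least 24 visits, and the cross-sectional monthly mean
#' and sd of the z-score (ages binned to the nearest integer month, ties to
#' even, bins 0-24).
#'
#' @param cohort a `growth_cohort` data.frame.
#' @return object of class `cohort_summary` (a named list per site).
#' @export
cohort_summary <- function(cohort) {
  cohort <- as.data.frame(cohort)
  if (!nrow(cohort)) stop("empty cohort")
  out <- lapply(split(cohort, cohort$site), function(d) {
    visits <- table(d$child_id)
    month <- round(d$age_months)
    month <- month[month <= 24]
    zw <- d$zwfl[round(d$age_months) <= 24]
    monthly <- data.frame(
      month = sort(unique(month)),
      mean = as.numeric(tapply(zw, month, mean)),
      sd = as.numeric(tapply(zw, month, stats::sd)),
      n = as.integer(table(month)))
    list(n_children = length(visits),
         visit_counts = visits,
         mean_visits = mean(visits),
         share_ge24 = mean(visits >= 24),
         monthly = monthly)
  })
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  for (site in names(x)) {
    s <- x[[site]]
    cat(sprintf(
      "site %s: %d children, mean %.1f visits, share >=24 visits %.2f\n",
      site, s$n_children, s$mean_visits, s$share_ge24))
    cat(sprintf("  monthly zwfl mean range: [%.2f, %.2f]\n",
                min(s$monthly$mean), max(s$monthly$mean)))
  }
  invisible(x)
}

format_summary <- function(sm) {
  unlist(lapply(names(sm), function(site) {
    s <- sm[[site]]
    c(sprintf("site %s: n_children=%d mean_visits=%.3f share_ge24=%.3f",
              site, s$n_children, s$mean_visits, s$share_ge24),
      sprintf("  month %2d: mean=%.4f sd=%.4f n=%d", s$monthly$month,
              s$monthly$mean, s$monthly$sd, s$monthly$n))
  }))
}

# deterministic hash of an R object (provenance stamping): polynomial
# rolling hash over the serialised bytes, exact in double precision
config_hash <- function(x) {
  b <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  m <- 2147483647
  for (i in seq_along(b)) h <- (h * 257 + b[i]) %% m
  sprintf("%08x", as.integer(h))
}

fit_to_list <- function(fit) {
  list(family = fit$family,
       estimates = as.list(fit$estimates),
       standard_errors = as.list(fit$standard_errors),
       loglik = fit$loglik, n_params = fit$n_params, n_obs = fit$n_obs,
       aic = fit$aic, bic = fit$bic, converged = fit$converged,
       random_effects_cov = if (!is.null(fit$random_effects_cov_hat))
         as.data.frame(fit$random_effects_cov_hat),
       empirical_bayes = if (!is.null(fit$empirical_bayes))
         cbind(child_id = rownames(fit$empirical_bayes),
               fit$empirical_bayes))
}

#' Run a simulate / fit / predict pipeline from a configuration
#'
#' Executes the configured stages in order and writes their artifacts to
#' `output_dir`: `cohort.csv` (simulate, or a validated copy of input
#' data), `summary.txt` (summarize), `fit.json` (fit), `field.csv`
#' (predict).  Every output carries a provenance line with the package
#' version, the seed and a hash of the configuration.  All randomness flows
#' from `config$seed`; running the same configuration twice produces
#' byte-identical outputs.  A failing stage halts the pipeline with an
#' error naming that stage.
#'
#' @param config a named list (or path to a YAML file) with entries `seed`,
#'   optionally `data` (input cohort CSV when not simulating), and a
#'   `stages` list with any of:
#'   \describe{
#'     \item{simulate}{`list(model = <model config>, design = <cohort_design
#'       arguments>)`}
#'     \item{fit}{`list(kind = "sde"|"mixed"|"lmm"|"baseline", model =
#'       <model config>, parameterization, re_names, re_cov, spec = <lmm
#'       arguments>, options)`}
#'     \item{predict}{`list(site, grid = <prediction_grid arguments>)`}
#'     \item{summarize}{`TRUE`}
#'   }
#' @param output_dir directory for artifacts (created if needed); defaults
#'   to `config$output_dir`.
#' @return named list of written file paths, invisibly; the computed
#'   objects are attached as attributes `cohort`, `fit`, `field`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  output_dir <- output_dir %||% config$output_dir %||% stop(
    "no output directory: set 'output_dir'")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  cfg_hashed <- config
  cfg_hashed$output_dir <- NULL   # hash the analysis, not where it ran
  stamp <- sprintf("growthsde %s seed=%d config_hash=%s",
                   as.character(utils::packageVersion("growthsde")),
                   as.integer(seed), config_hash(cfg_hashed))
  stages <- config$stages %||% list()
  paths <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- NULL
  if (!is.null(stages$simulate)) {
    cohort <- run_stage("simulate", {
      model <- model_from_config(stages$simulate$model)
      design_args <- stages$simulate$design
      design_args$seed <- design_args$seed %||% seed
      if (!is.null(design_args$random_effects_cov))
        design_args$random_effects_cov <-
          unlist(design_args$random_effects_cov)
      design_args$sites <- as.character(unlist(design_args$sites %||%
                                                 c("SiteA", "SiteB")))
      design_args$visit_ages <- as.numeric(unlist(design_args$visit_ages %||%
                                                    0:24))
      design <- do.call(cohort_design, design_args)
      simulate_cohort(model, design)
    })
    paths$cohort <- file.path(output_dir, "cohort.csv")
    write_cohort(cohort, paths$cohort, provenance = stamp)
  } else if (!is.null(config$data)) {
    cohort <- run_stage("read", read_cohort(config$data))
    paths$cohort <- file.path(output_dir, "cohort.csv")
    write_cohort(cohort, paths$cohort, provenance = stamp)
  }

  if (isTRUE(stages$summarize)) {
    if (is.null(cohort)) stop("pipeline stage 'summarize' failed: no cohort")
    paths$summary <- file.path(output_dir, "summary.txt")
    con <- file(paths$summary, open = "wb")
    writeLines(c(paste0("# ", stamp), format_summary(cohort_summary(cohort))),
               con)
    close(con)
  }

  fit <- NULL
  if (!is.null(stages$fit)) {
    if (is.null(cohort)) stop("pipeline stage 'fit' failed: no cohort")
    fit <- run_stage("fit", {
      fcfg <- stages$fit
      kind <- fcfg$kind %||% "sde"
      opts <- fcfg$options %||% list()
      switch(kind,
        sde = fit_mle(model_from_config(fcfg$model), cohort,
                      parameterization = fcfg$parameterization %||%
                        "natural", options = opts),
        mixed = fit_mixed_sde(model_from_config(fcfg$model), cohort,
                              re_names = as.character(unlist(fcfg$re_names)),
                              re_cov_structure = fcfg$re_cov %||% "diagonal",
                              parameterization = fcfg$parameterization %||%
                                "natural", options = opts),
        lmm = fit_lmm(do.call(lmm_spec, fcfg$spec), cohort, options = opts),
        baseline = fit_linear_baseline(cohort, type = fcfg$type %||%
                                         "transition"),
        stop("unknown fit kind '", kind, "'"))
    })
    paths$fit <- file.path(output_dir, "fit.json")
    jsonlite::write_json(c(list(provenance = stamp), fit_to_list(fit)),
                         paths$fit, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }

  if (!is.null(stages$predict)) {
    if (is.null(fit)) stop("pipeline stage 'predict' failed: no fit")
    field <- run_stage("predict", {
      pcfg <- stages$predict
      grid_args <- pcfg$grid %||% list()
      grid_args$ages <- as.numeric(unlist(grid_args$ages %||% 0:24))
      grid_args$values <- as.numeric(unlist(grid_args$values %||%
                                              seq(-4, 3, 0.5)))
      grid <- do.call(prediction_grid, grid_args)
      predict_field(fit, cohort, grid, site = pcfg$site,
                    seed = pcfg$seed %||% (seed + 1L))
    })
    paths$field <- file.path(output_dir, "field.csv")
    export_field(field, paths$field, provenance = stamp)
    attr(paths, "field") <- field
  }
  attr(paths, "cohort") <- cohort
  attr(paths, "fit") <- fit
  invisible(paths)
}
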