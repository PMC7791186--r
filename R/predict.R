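# Grid-based prediction of future trajectories.
#
# Each fitted child contributes a parameter set (fixed effects + its
# empirical-Bayes random effects).  For a grid point (age, z) we score every
# child by the slice-density value of that point for a process started at
# the child's own first observation ("locality").  A predicted path walks
# forward in small age steps: at each step the currently most likely
# parameter set is re-selected and the state moves to the slice mean of the
# chosen set over the step.  Splitting children into 10 seeded random
# groups and repeating the walk within each group yields 10 sensitivity
# paths alongside the main one.

#' Prediction grid
#'
#' Starting points are all combinations of `ages` and `values`; from each,
#' a path is stepped forward by `step` months up to `horizon`.
#'
#' @param ages increasing starting ages (months).
#' @param values starting z-score values.
#' @param step prediction increment, months (> 0).
#' @param horizon final age, months.
#' @return object of class `prediction_grid`.
#' @export
prediction_grid <- function(ages = 0:24, values = seq(-4, 3, by = 0.5),
                            step = 0.1, horizon = 24) {
  if (step <= 0) stop("'step' must be > 0")
  if (any(diff(ages) <= 0)) stop("'ages' must be increasing")
  structure(list(ages = ages, values = values, step = step,
                 horizon = horizon),
            class = "prediction_grid")
}

# per-child natural parameters + first observation, for one site
child_param_table <- function(fit, cohort, site) {
  stopifnot(inherits(fit, "growth_fit"))
  if (is.null(fit$fitspec))
    stop("prediction needs an SDE fit carrying its parameter map")
  trans <- build_transitions(cohort)
  if (!identical(trans$children, fit$children))
    stop("cohort does not match the one the model was fitted to")
  d <- fit$fitspec$d
  B <- if (d > 0L && !is.null(fit$empirical_bayes))
    as.matrix(fit$empirical_bayes)
  else if (d > 0L) matrix(0, trans$n_children, d)
  else NULL
  theta <- fit$transformed
  P <- fs_child_params(fit$fitspec, theta, trans$site_of_child, B)
  sel <- trans$site_of_child == site
  if (!any(sel)) stop("no children for site '", site, "'")
  list(children = trans$children[sel],
       P = P[sel, , drop = FALSE],
       first_age = trans$first_age[sel],
       first_val = trans$first_val[sel])
}

locality_kernel <- function(tab, age, value, eps = 1e-9) {
  n <- length(tab$children)
  scores <- numeric(n)
  started <- tab$first_age <= age + eps
  anchored <- abs(tab$first_age - age) <= eps
  live <- started & !anchored
  if (any(live)) {
    P <- tab$P[live, , drop = FALSE]
    mo <- slice_moments(tab$first_age[live], rep(age, sum(live)),
                        tab$first_val[live],
                        P[, 1L], P[, 2L], P[, 3L], P[, 4L], P[, 5L],
                        P[, 6L])
    scores[live] <- stats::dnorm(value, mo$mean, sqrt(mo$var))
  }
  # degenerate slice at dt = 0: the child's own anchor is the density's
  # supremum (+Inf sentinel); any other value has zero density
  scores[anchored] <- ifelse(abs(tab$first_val[anchored] - value) <= eps,
                             Inf, 0)
  names(scores) <- tab$children
  scores
}

#' Likelihood-based locality scores at a grid point
#'
#' For every child of `site`, the slice-density value of the grid point
#' `(age, value)` for a process started at that child's first observed
#' (age, value) under the child's parameter set (fixed effects plus its
#' empirical-Bayes random effects).  Children whose first observation is
#' later than `age` score 0 (excluded); a child whose own anchor coincides
#' with the grid point scores `+Inf` (the degenerate density's supremum),
#' ranking it first.
#'
#' @param fit a `growth_fit` from [fit_mixed_sde()] (a fixed-effects
#'   [fit_mle()] fit works too: all children then share one parameter set).
#' @param cohort the cohort the model was fitted to.
#' @param age,value the grid point (months, z-score).
#' @param site site label.
#' @return named numeric vector of scores, one per child.
#' @export
locality_scores <- function(fit, cohort, age, value, site) {
  tab <- child_param_table(fit, cohort, site)
  locality_kernel(tab, age, value)
}

walk_path <- function(tab, idx, a0, v0, step, horizon) {
  nmax <- ceiling((horizon - a0) / step) + 1L
  ages <- numeric(nmax)
  values <- numeric(nmax)
  chosen <- character(nmax)
  ages[1L] <- a0
  values[1L] <- v0
  chosen[1L] <- NA_character_
  k <- 1L
  t <- a0
  x <- v0
  sub <- list(children = tab$children[idx],
              P = tab$P[idx, , drop = FALSE],
              first_age = tab$first_age[idx],
              first_val = tab$first_val[idx])
  while (t < horizon - 1e-9) {
    sc <- locality_kernel(sub, t, x)
    if (!any(sc > 0)) {
      warning("no candidate parameter set at age ", signif(t, 4),
              "; path truncated")
      break
    }
    j <- which.max(sc)
    dt <- min(step, horizon - t)
    mo <- slice_moments(t, t + dt, x,
                        sub$P[j, 1L], sub$P[j, 2L], sub$P[j, 3L],
                        sub$P[j, 4L], sub$P[j, 5L], sub$P[j, 6L])
    t <- t + dt
    x <- mo$mean
    k <- k + 1L
    ages[k] <- t
    values[k] <- x
    chosen[k] <- sub$children[j]
  }
  list(path = data.frame(age = ages[seq_len(k)],
                         predicted_value = values[seq_len(k)]),
       chosen = chosen[seq_len(k)])
}

#' Predict future trajectories from a grid of starting points
#'
#' For each starting point of the grid, computes the main predicted path to
#' the horizon (locality-ranked parameter selection re-evaluated at every
#' step, forward stepping by the slice-density mean) plus 10 sensitivity
#' paths obtained by partitioning the site's children into 10 seeded random
#' groups and running the same walk within each group.
#'
#' @inheritParams locality_scores
#' @param grid a [prediction_grid()].
#' @param seed integer seed for the 10-fold grouping (the walk itself is
#'   deterministic).
#' @return object of class `prediction_field`: per start, `main_path`, the
#'   list `sensitivity_paths` (fold1..fold10) and `chosen_child_ids` along
#'   the main path.
#' @export
predict_field <- function(fit, cohort, grid, site, seed = 1L) {
  stopifnot(inherits(grid, "prediction_grid"))
  tab <- child_param_table(fit, cohort, site)
  n <- length(tab$children)
  n_folds <- 10L
  folds <- with_private_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  starts <- expand.grid(start_age = grid$ages, start_value = grid$values,
                        KEEP.OUT.ATTRS = FALSE)
  results <- vector("list", nrow(starts))
  for (g in seq_len(nrow(starts))) {
    a0 <- starts$start_age[g]
    v0 <- starts$start_value[g]
    main <- walk_path(tab, seq_len(n), a0, v0, grid$step, grid$horizon)
    sens <- lapply(seq_len(n_folds), function(fd) {
      walk_path(tab, which(folds == fd), a0, v0, grid$step,
                grid$horizon)$path
    })
    names(sens) <- paste0("fold", seq_len(n_folds))
    results[[g]] <- list(start_age = a0, start_value = v0,
                         main_path = main$path,
                         sensitivity_paths = sens,
                         chosen_child_ids = main$chosen)
  }
  structure(list(starts = starts, results = results, site = site,
                 seed = seed, grid = grid, folds = folds),
            class = "prediction_field")
}

#' @export
print.prediction_field <- function(x, ...) {
  cat(sprintf(
    "prediction field: %d start(s), site %s, step %g months, horizon %g\n",
    nrow(x$starts), x$site, x$grid$step, x$grid$horizon))
  invisible(x)
}

field_rows <- function(field) {
  out <- lapply(field$results, function(r) {
    main <- cbind(start_age = r$start_age, start_value = r$start_value,
                  path_kind = "main", r$main_path)
    folds <- lapply(names(r$sensitivity_paths), function(nm)
      cbind(start_age = r$start_age, start_value = r$start_value,
            path_kind = nm, r$sensitivity_paths[[nm]]))
    do.call(rbind, c(list(main), folds))
  })
  do.call(rbind, out)
}

#' Export / read back a prediction field
#'
#' `export_field()` writes the tidy long form (`start_age, start_value,
#' path_kind, age, predicted_value`, with `path_kind` one of `main`,
#' `fold1` ... `fold10`) as CSV with full floating-point precision, so a
#' read round-trip reproduces the paths exactly.  `read_field()` parses
#' such a file back into a `prediction_field`-shaped object.
#'
#' @param field a `prediction_field`.
#' @param path output CSV path.
#' @param provenance optional character line written as a leading `#`
#'   comment.
#' @return `export_field()` the path invisibly; `read_field()` a
#'   `prediction_field` (without per-step chosen child ids, which the tidy
#'   format does not carry).
#' @export
export_field <- function(field, path, provenance = NULL) {
  stopifnot(inherits(field, "prediction_field"))
  rows <- field_rows(field)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(if (!is.null(provenance)) paste0("# ", provenance),
               "start_age,start_value,path_kind,age,predicted_value"),
             con)
  writeLines(paste(num17(rows$start_age), num17(rows$start_value),
                   rows$path_kind, num17(rows$age),
                   num17(rows$predicted_value), sep = ","),
             con)
  invisible(path)
}

num17 <- function(x) sprintf("%.17g", x)

#' @rdname export_field
#' @export
read_field <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  req <- c("start_age", "start_value", "path_kind", "age",
           "predicted_value")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("field file missing column(s): ", paste(missing, collapse = ", "))
  key <- paste(df$start_age, df$start_value)
  starts <- unique(df[c("start_age", "start_value")])
  results <- lapply(seq_len(nrow(starts)), function(g) {
    sel <- df[key == paste(starts$start_age[g], starts$start_value[g]), ]
    main <- sel[sel$path_kind == "main", c("age", "predicted_value")]
    rownames(main) <- NULL
    folds <- lapply(paste0("fold", 1:10), function(nm) {
      p <- sel[sel$path_kind == nm, c("age", "predicted_value")]
      rownames(p) <- NULL
      p
    })
    names(folds) <- paste0("fold", 1:10)
    list(start_age = starts$start_age[g],
         start_value = starts$start_value[g],
         main_path = main, sensitivity_paths = folds,
         chosen_child_ids = NULL)
  })
  rownames(starts) <- NULL
  structure(list(starts = starts, results = results, site = NA_character_,
                 seed = NA_integer_, grid = NULL, folds = NULL),
            class = "prediction_field")
}
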