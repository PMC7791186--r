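# Grid-based prediction: locality scoring, path walking, export.

# exported representation, for byte-level comparisons
field_rows_public <- function(field) {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  export_field(field, path)
  readLines(path)
}

# two well-separated OU regimes fitted with a random long-term mean
two_cluster_fit <- function(n_per = 20, betas = c(-2, 1), alpha = 1.5,
                            sigma = 0.4, seed = 201) {
  cohs <- lapply(seq_along(betas), function(k) {
    m <- ou_model(alpha, betas[k], sigma)
    d <- cohort_design(n_per, sites = "A", visit_ages = 0:20,
                       init_mean = betas[k], init_sd = 0.3,
                       seed = seed + k)
    coh <- simulate_cohort(m, d)
    coh$child_id <- sprintf("g%d_%s", k, coh$child_id)
    coh
  })
  coh <- as_growth_cohort(do.call(rbind, cohs))
  fit <- fit_mixed_sde(ou_model(1, 0, 1), coh, re_names = "beta",
                       parameterization = "ou",
                       options = list(restarts = 1))
  list(cohort = coh, fit = fit)
}

test_that("locality scores equal the brute-force density composition", {
  coh <- small_ou_cohort(n = 15, visits = 0:10, seed = 202)
  f <- fit_mle(ou_model(1, 0, 1), coh, parameterization = "ou",
               options = list(restarts = 1))
  sc <- locality_scores(f, coh, age = 12, value = -0.5, site = "A")
  al <- f$estimates[["alpha"]]; be <- f$estimates[["beta"]]
  si <- f$estimates[["sigma"]]
  m <- ou_model(al, be, si)
  for (id in names(sc)) {
    tr <- coh[coh$child_id == id, ]
    d <- slice_density(m, tr$zwfl[1], tr$age_months[1], 12)
    expect_equal(sc[[id]], dnorm(-0.5, d$mean, sqrt(d$variance)),
                 tolerance = 1e-10)
  }
})

test_that("anchors and unborn children get the sentinel scores", {
  coh <- as_growth_cohort(data.frame(
    child_id = rep(c("early", "late"), each = 3),
    site = "A",
    age_months = c(0, 1, 2, 6, 7, 8),
    zwfl = c(-1, -1.1, -0.9, 0.5, 0.6, 0.4)))
  f <- fit_mle(ou_model(1, 0, 1), coh, parameterization = "ou",
               options = list(restarts = 1))
  # grid point exactly on a child's first observation: +Inf sentinel
  sc <- locality_scores(f, coh, age = 0, value = -1, site = "A")
  expect_identical(sc[["early"]], Inf)
  expect_identical(sc[["late"]], 0)   # first age 6 > 0: excluded
  # same age, different value: degenerate density gives 0
  sc2 <- locality_scores(f, coh, age = 0, value = 2, site = "A")
  expect_identical(sc2[["early"]], 0)
})

test_that("locality prefers the child whose trajectory is nearby", {
  res <- two_cluster_fit()
  sc <- locality_scores(res$fit, res$cohort, age = 10, value = -2,
                        site = "A")
  low <- grepl("^g1", names(sc))
  expect_gt(min(sc[low]), max(sc[!low]))
})

test_that("a single-child cohort predicts its own mean path", {
  coh <- small_ou_cohort(n = 1, visits = 0:20, seed = 203)
  f <- fit_mle(ou_model(1, 0, 1), coh, parameterization = "ou",
               options = list(restarts = 1))
  grid <- prediction_grid(ages = 2, values = -1.5, step = 0.5, horizon = 10)
  # 9 of the 10 folds hold no child at all: their paths truncate with a
  # warning at the start point
  field <- suppressWarnings(predict_field(f, coh, grid, site = "A",
                                          seed = 1))
  m <- ou_model(f$estimates[["alpha"]], f$estimates[["beta"]],
                f$estimates[["sigma"]])
  oracle <- mean_path(m, -1.5, 2, 10, 0.5)
  got <- field$results[[1]]$main_path
  expect_equal(got$age, oracle$age, tolerance = 1e-12)
  expect_equal(got$predicted_value, oracle$predicted_value,
               tolerance = 1e-10)
  # and every path starts at the grid point
  expect_equal(got$predicted_value[1], -1.5)
  for (p in field$results[[1]]$sensitivity_paths)
    expect_equal(p$predicted_value[1], -1.5)
  w <- capture_warnings(predict_field(f, coh, grid, site = "A", seed = 1))
  expect_true(any(grepl("truncated", w)))
})

test_that("identical parameter sets make all 11 paths identical", {
  coh <- small_ou_cohort(n = 12, visits = 0:15, seed = 204)
  f <- fit_mle(ou_model(1, 0, 1), coh, parameterization = "ou",
               options = list(restarts = 1))  # no random effects: one set
  grid <- prediction_grid(ages = 1, values = 0.5, step = 0.25, horizon = 12)
  field <- predict_field(f, coh, grid, site = "A", seed = 3)
  main <- field$results[[1]]$main_path
  for (p in field$results[[1]]$sensitivity_paths)
    expect_equal(p$predicted_value, main$predicted_value, tolerance = 1e-12)
})

test_that("prediction is deterministic given fit, grid and seed", {
  res <- two_cluster_fit(n_per = 10)
  grid <- prediction_grid(ages = c(1, 6), values = c(-2, 1), step = 0.5,
                          horizon = 15)
  f1 <- predict_field(res$fit, res$cohort, grid, site = "A", seed = 9)
  f2 <- predict_field(res$fit, res$cohort, grid, site = "A", seed = 9)
  expect_identical(field_rows_public(f1), field_rows_public(f2))
})

test_that("halving the step barely moves the terminal prediction", {
  res <- two_cluster_fit(n_per = 10)
  for (st in c(0.2, 0.1)) {
    grid <- prediction_grid(ages = 2, values = -1.5, step = st,
                            horizon = 24)
    fld <- predict_field(res$fit, res$cohort, grid, site = "A", seed = 5)
    term <- tail(fld$results[[1]]$main_path$predicted_value, 1)
    if (st == 0.2) term_coarse <- term else term_fine <- term
  }
  expect_lt(abs(term_coarse - term_fine), 0.05)
})

test_that("export and re-import reproduce the field exactly", {
  res <- two_cluster_fit(n_per = 8)
  grid <- prediction_grid(ages = c(1, 4), values = c(-2, 1), step = 0.5,
                          horizon = 10)
  field <- predict_field(res$fit, res$cohort, grid, site = "A", seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  export_field(field, path, provenance = "test")
  back <- read_field(path)
  expect_equal(nrow(back$starts), 4L)
  for (g in seq_along(field$results)) {
    expect_equal(back$results[[g]]$main_path,
                 field$results[[g]]$main_path)
    expect_equal(back$results[[g]]$sensitivity_paths,
                 field$results[[g]]$sensitivity_paths)
  }
  # row count: 11 paths per start, each start's step count fixed by the
  # grid arithmetic (all paths ran to the horizon)
  expected <- sum(vapply(field$results, function(r)
    11 * ((10 - r$start_age) / 0.5 + 1), numeric(1)))
  expect_equal(nrow(read.csv(path, comment.char = "#")), expected)
})

test_that("the bundled plotting script consumes an exported field", {
  skip_if_not_installed("ggplot2")
  res <- two_cluster_fit(n_per = 8)
  grid <- prediction_grid(ages = 1, values = c(-2, 1), step = 0.5,
                          horizon = 8)
  field <- predict_field(res$fit, res$cohort, grid, site = "A", seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  export_field(field, path)
  script <- system.file("scripts", "plot-field.R", package = "growthsde")
  env <- new.env()
  sys.source(script, envir = env)
  p <- env$plot_field_csv(path)
  expect_s3_class(p, "ggplot")
})
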