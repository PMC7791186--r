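# The linear-SDE family: drift evaluation, closed-form slice densities,
# and the OU covariance function.

test_that("drift evaluates p(t) + a1*x, with the OU special case", {
  ou <- ou_model(alpha = 1, beta = 0, sigma = 1)
  expect_equal(drift(ou, t = 0, x = 2), -2)
  # any model is at rest at the root of its linear drift
  m <- sde_model(1, TRUE, c(a1 = -0.7, a2 = 0.3, a3 = 0.02, s = 0.5))
  t <- 7
  x_star <- (0.3 + 0.02 * t) / 0.7
  expect_equal(drift(m, t, x_star), 0)
  # cubic drift against an independent polynomial evaluation
  a <- c(-0.5, 0.1, 0.02, -0.003, 0.0001)
  cub <- sde_model(3, TRUE, c(a1 = a[1], a2 = a[2], a3 = a[3], a4 = a[4],
                              a5 = a[5], s = 1))
  t <- 12; x <- -1
  horner <- a[2] + t * (a[3] + t * (a[4] + t * a[5])) + a[1] * x
  expect_equal(drift(cub, t, x), horner, tolerance = 1e-14)
})

test_that("unknown site labels are rejected by name", {
  m <- sde_model(0, TRUE, c(a1 = -1, a2 = 0, s = 1),
                 site_offsets = list(a2 = c(A = 0, B = 0.2)))
  expect_error(drift(m, 1, 0, site = "Venda"), "Venda")
  expect_silent(drift(m, 1, 0, site = "B"))
})

test_that("slice density matches the printed OU transition law", {
  ou <- ou_model(alpha = 2, beta = 0, sigma = 1)
  d <- slice_density(ou, x0 = 1, t0 = 0, t1 = 0.3)
  expect_equal(d$mean, 0.5488, tolerance = 1e-4)
  expect_equal(d$variance, 0.1747, tolerance = 1e-3)
  set.seed(101)
  for (i in 1:25) {
    al <- runif(1, 0.2, 3); be <- runif(1, -2, 1); si <- runif(1, 0.2, 1.5)
    t0 <- runif(1, 0, 12); t1 <- t0 + runif(1, 0.05, 4)
    x0 <- rnorm(1)
    d <- slice_density(ou_model(al, be, si), x0, t0, t1)
    oracle <- ou_slice_printed(al, be, si, x0, t0, t1)
    expect_equal(d$mean, oracle$mean, tolerance = 1e-12)
    expect_equal(d$variance, oracle$var, tolerance = 1e-12)
  }
})

test_that("slice density matches the printed cubic-drift closed form", {
  set.seed(202)
  for (i in 1:25) {
    m <- random_cubic_model()
    a <- unname(m$params[paste0("a", 1:5)])
    t0 <- runif(1, 0, 12); t1 <- t0 + runif(1, 0.05, 3)
    x0 <- rnorm(1)
    d <- slice_density(m, x0, t0, t1)
    oracle <- poly_slice_printed(a, m$params[["s"]], x0, t0, t1)
    expect_equal(d$mean, oracle$mean,
                 tolerance = 1e-9 * max(1, abs(oracle$mean)))
    expect_equal(d$variance, oracle$var, tolerance = 1e-11)
  }
})

test_that("degenerate, stationary and reversed-time slices behave", {
  ou <- ou_model(1, -0.5, 1)
  d0 <- slice_density(ou, x0 = 0.7, t0 = 3, t1 = 3)
  expect_identical(d0$variance, 0)
  expect_equal(d0$mean, 0.7)
  dinf <- slice_density(ou, x0 = 3, t0 = 0, t1 = 60)
  expect_equal(dinf$mean, -0.5, tolerance = 1e-12)
  expect_equal(dinf$variance, 0.5, tolerance = 1e-12)
  expect_error(slice_density(ou, 0, t0 = 2, t1 = 1), "backwards")
})

test_that("slice variance strictly increases with elapsed time", {
  set.seed(7)
  for (m in list(random_ou_model(), random_cubic_model(),
                 sde_model(1, FALSE, c(a2 = 0.1, a3 = -0.01, s = 0.8)))) {
    dts <- seq(0.1, 6, by = 0.1)
    v <- vapply(dts, function(dt) slice_density(m, 0, 2, 2 + dt)$variance,
                numeric(1))
    expect_true(all(diff(v) > 0))
  }
})

test_that("no-mean-reversion models use the a1 -> 0 limit forms", {
  m <- sde_model(2, FALSE, c(a2 = 0.3, a3 = -0.05, a4 = 0.002, s = 0.7))
  t0 <- 2; t1 <- 5; x0 <- -1
  d <- slice_density(m, x0, t0, t1)
  pint <- integrate(function(u) 0.3 - 0.05 * u + 0.002 * u^2, t0, t1,
                    rel.tol = 1e-12)$value
  expect_equal(d$mean, x0 + pint, tolerance = 1e-10)
  expect_equal(d$variance, 0.7^2 * (t1 - t0), tolerance = 1e-12)
})

test_that("slice density is continuous across a1 = 0", {
  base <- c(a2 = 0.2, a3 = -0.03, a4 = 1e-3, a5 = -1e-5)
  m0 <- sde_model(3, FALSE, c(base, s = 0.6))
  d0 <- slice_density(m0, x0 = 1.3, t0 = 1, t1 = 4)
  for (a1 in c(1e-8, -1e-8)) {
    m <- sde_model(3, TRUE, c(a1 = a1, base, s = 0.6))
    d <- slice_density(m, x0 = 1.3, t0 = 1, t1 = 4)
    expect_lt(abs(d$mean - d0$mean), 1e-6)
    expect_lt(abs(d$variance - d0$variance), 1e-6)
  }
})

test_that("Chapman-Kolmogorov composition holds for random models", {
  set.seed(303)
  for (i in 1:20) {
    m <- if (i %% 2) random_ou_model() else random_cubic_model()
    t0 <- runif(1, 0, 10)
    tm <- t0 + runif(1, 0.1, 2)
    t1 <- tm + runif(1, 0.1, 2)
    x0 <- rnorm(1)
    d01 <- slice_density(m, x0, t0, t1)
    d0m <- slice_density(m, x0, t0, tm)
    # the slice mean is affine in the state, so composing the two Gaussian
    # stages gives mean m2(m1(x0)) and variance v2 + (dm2/dx)^2 v1
    dm1 <- slice_density(m, d0m$mean, tm, t1)
    slope <- exp(m$params[["a1"]] * (t1 - tm))
    comp_var <- dm1$variance + slope^2 * d0m$variance
    expect_equal(dm1$mean, d01$mean,
                 tolerance = 1e-10 * max(1, abs(d01$mean)))
    expect_equal(comp_var, d01$variance, tolerance = 1e-10 * d01$variance)
  }
})

test_that("polynomial slice density reduces to the OU law", {
  set.seed(404)
  for (i in 1:20) {
    al <- runif(1, 0.2, 2); be <- runif(1, -2, 1); si <- runif(1, 0.3, 1)
    poly <- sde_model(3, TRUE, c(a1 = -al, a2 = al * be, a3 = 0, a4 = 0,
                                 a5 = 0, s = si))
    ou <- ou_model(al, be, si)
    t0 <- runif(1, 0, 12); t1 <- t0 + runif(1, 0.05, 4); x0 <- rnorm(1)
    dp <- slice_density(poly, x0, t0, t1)
    du <- slice_density(ou, x0, t0, t1)
    expect_equal(dp$mean, du$mean, tolerance = 1e-12)
    expect_equal(dp$variance, du$variance, tolerance = 1e-12)
  }
})

test_that("OU covariance matches its printed formula and symmetries", {
  ou <- ou_model(1, 0, 1)
  expect_equal(ou_covariance(ou, t0 = 1, s_time = 1, t_time = 1), 0)
  expect_equal(ou_covariance(ou, 0, 0.5, 1.0),
               exp(-1.5) * (exp(1) - 1) / 2, tolerance = 1e-14)
  expect_equal(ou_covariance(ou, 0, 0.5, 1.0), ou_covariance(ou, 0, 1.0, 0.5))
  expect_error(ou_covariance(sde_model(1, FALSE, c(a2 = 0.1, a3 = 0, s = 1)),
                             0, 1, 2), "OU")
  expect_error(ou_covariance(ou, t0 = 2, s_time = 1, t_time = 3), "t0")
})

test_that("OU covariance matches exactly simulated path pairs", {
  ou <- ou_model(1, 0, 1)
  n <- 3e5
  set.seed(505)
  d1 <- slice_density(ou, x0 = 0.4, t0 = 0, t1 = 0.5)
  x1 <- rnorm(n, d1$mean, sqrt(d1$variance))
  # exact transition from each x1 to t = 1: mean is affine in x1
  m2 <- exp(-0.5) * x1
  v2 <- slice_density(ou, 0, 0, 0.5)$variance  # same dt, state-free variance
  x2 <- rnorm(n, m2, sqrt(v2))
  emp <- cov(x1, x2)
  mc_se <- sd((x1 - mean(x1)) * (x2 - mean(x2))) / sqrt(n)
  expect_lt(abs(emp - ou_covariance(ou, 0, 0.5, 1.0)), 3 * mc_se)
})

test_that("model specifications round-trip through YAML config files", {
  m <- sde_model(2, TRUE,
                 c(a1 = -0.6, a2 = 0.25, a3 = -0.01, a4 = 5e-4, s = 0.55),
                 site_offsets = list(a2 = c(A = 0, B = 0.15),
                                     s = c(A = 0, B = -0.2)),
                 random_effect_names = c("a2", "s"))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(m, path)
  m2 <- read_model_config(path)
  expect_equal(m2$params, m$params)
  expect_equal(m2$drift_order, m$drift_order)
  expect_equal(m2$mean_reversion, m$mean_reversion)
  expect_equal(lapply(m2$site_offsets, as.numeric),
               lapply(m$site_offsets, as.numeric))
  expect_equal(m2$random_effect_names, m$random_effect_names)
})

test_that("model invariants are enforced", {
  expect_error(sde_model(0, TRUE, c(a1 = -1, a2 = 0, s = -0.1)), "> 0")
  expect_error(sde_model(0, FALSE, c(a1 = -1, a2 = 0, s = 1)), "unused")
  expect_error(sde_model(1, TRUE, c(a1 = -1, a2 = 0, s = 1)), "missing")
  expect_error(ou_model(-1, 0, 1), "alpha")
  # cubic + mean reversion carries exactly (a1..a5, s)
  m <- sde_model(3, TRUE, c(a1 = -0.5, a2 = 0.1, a3 = 0.01, a4 = -1e-3,
                            a5 = 1e-4, s = 1))
  expect_named(m$params, c("a1", "a2", "a3", "a4", "a5", "s"))
})
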