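# Exact and Euler-Maruyama simulation, and the synthetic-cohort generator.

test_that("exact transition sampling is degenerate-correct and unbiased", {
  ou <- ou_model(1, -0.5, 0.8)
  expect_identical(sample_transition(ou, x0 = 0.3, t0 = 2, t1 = 2), 0.3)
  # essentially noise-free diffusion returns the slice mean
  tiny <- ou_model(1, -0.5, 1e-12)
  d <- slice_density(tiny, 1, 0, 1)
  expect_equal(sample_transition(tiny, 1, 0, 1), d$mean, tolerance = 1e-9)
  set.seed(11)
  d <- slice_density(ou, 1, 0, 1)
  draws <- sample_transition(ou, 1, 0, 1, n = 1e4)
  se <- sqrt(d$variance / 1e4)
  expect_lt(abs(mean(draws) - d$mean), 4 * se)
  # reproducible under a fixed seed
  set.seed(99); a <- sample_transition(ou, 0, 0, 1, n = 5)
  set.seed(99); b <- sample_transition(ou, 0, 0, 1, n = 5)
  expect_identical(a, b)
})

test_that("Euler-Maruyama is exact when deterministic and converges", {
  still <- sde_model(0, FALSE, c(a2 = 0, s = 1))
  still$params[["s"]] <- 0  # zero-diffusion edge case, deterministic Euler
  expect_identical(euler_maruyama(still, x0 = 1.2, t0 = 0, t1 = 1,
                                  step = 0.1), 1.2)
  m <- sde_model(1, TRUE, c(a1 = -0.5, a2 = 0.3, a3 = 0.02, s = 1))
  m$params[["s"]] <- 0
  one <- euler_maruyama(m, x0 = -1, t0 = 2, t1 = 2.5, step = 0.5 - 1e-12)
  expect_equal(one, -1 + drift(m, 2, -1) * (0.5 - 1e-12), tolerance = 1e-9)
  expect_error(euler_maruyama(m, 0, 0, 1, step = 1), "smaller")
  expect_error(euler_maruyama(m, 0, 0, 1, step = 0), "> 0")
  # step halving moves endpoint moments toward the closed form
  ou <- ou_model(1.5, -1, 0.7)
  d <- slice_density(ou, 1, 0, 0.5)
  set.seed(21)
  coarse <- euler_maruyama(ou, 1, 0, 0.5, step = 5e-2, n = 4e4)
  fine <- euler_maruyama(ou, 1, 0, 0.5, step = 5e-3, n = 4e4)
  expect_lt(abs(mean(fine) - d$mean), abs(mean(coarse) - d$mean) + 3e-3)
  expect_lt(abs(var(fine) - d$variance), abs(var(coarse) - d$variance) + 3e-3)
})

test_that("exact sampler and Euler-Maruyama draw the same distribution", {
  set.seed(31)
  for (i in 1:5) {
    m <- if (i %% 2) random_ou_model() else random_cubic_model()
    t0 <- runif(1, 0, 6); dt <- runif(1, 0.3, 0.6); x0 <- rnorm(1)
    exact <- sample_transition(m, x0, t0, t0 + dt, n = 1e4)
    em <- euler_maruyama(m, x0, t0, t0 + dt, step = 1e-3, n = 1e4)
    expect_gt(suppressWarnings(ks.test(exact, em)$p.value), 0.01)
  }
})

test_that("trajectory simulation respects the schedule and the seed", {
  ou <- ou_model(1, 0, 0.5)
  tr <- simulate_trajectory(ou, ages = 0:24)
  expect_equal(nrow(tr), 25)
  expect_true(all(diff(tr$age_months) > 0))
  set.seed(5); a <- simulate_trajectory(ou, 0:10)
  set.seed(5); b <- simulate_trajectory(ou, 0:10)
  expect_identical(a, b)
  expect_error(simulate_trajectory(ou, numeric(0)), "empty")
  expect_error(simulate_trajectory(ou, c(0, 2, 2)), "increasing")
})

test_that("simulated lag covariances match the OU covariance function", {
  ou <- ou_model(1.2, 0, 0.8)
  n <- 2e5
  set.seed(41)
  # vectorised two-step exact simulation from a fixed start
  d1 <- slice_density(ou, 0.5, 0, 0.7)
  x1 <- rnorm(n, d1$mean, sqrt(d1$variance))
  lam <- exp(-1.2 * (1.5 - 0.7))
  v2 <- slice_density(ou, 0, 0.7, 1.5)$variance
  x2 <- rnorm(n, lam * x1, sqrt(v2))
  emp <- cov(x1, x2)
  mc_se <- sd((x1 - mean(x1)) * (x2 - mean(x2))) / sqrt(n)
  expect_lt(abs(emp - ou_covariance(ou, 0, 0.7, 1.5)), 4 * mc_se)
})

test_that("cohort generator delivers the designed structure", {
  ou <- ou_model(1, -0.5, 0.6)
  d <- cohort_design(10, sites = c("Haydom", "Venda"), seed = 7)
  coh <- simulate_cohort(ou, d)
  expect_s3_class(coh, "growth_cohort")
  expect_equal(length(unique(coh$child_id)), 20)
  expect_true(all(coh$site %in% c("Haydom", "Venda")))
  # same design + seed => identical cohort
  coh2 <- simulate_cohort(ou, d)
  expect_identical(as.data.frame(coh), as.data.frame(coh2))
})

test_that("visit jitter stays inside the 14-day window", {
  ou <- ou_model(1, 0, 0.5)
  d <- cohort_design(40, sites = "A", p_visit_missing = 0, seed = 8)
  coh <- simulate_cohort(ou, d)
  cap <- 14 / 30.4375
  for (tr in split(coh, coh$child_id)) {
    expect_equal(nrow(tr), 25)
    expect_true(all(abs(tr$age_months - 0:24) <= cap + 1e-12))
  }
})

test_that("missingness hits the designed completeness level", {
  ou <- ou_model(1, -0.5, 0.6)
  d <- cohort_design(600, sites = "A", p_visit_missing = 0.04, seed = 9)
  coh <- simulate_cohort(ou, d)
  visits <- table(coh$child_id)
  # binomial oracle: 24 non-anchor visits each kept w.p. 0.96
  exp_mean <- 1 + 24 * 0.96
  exp_ge24 <- pbinom(1, 24, 0.04)
  expect_lt(abs(mean(visits) - exp_mean),
            3 * sqrt(24 * 0.04 * 0.96 / 600))
  expect_lt(abs(mean(visits >= 24) - exp_ge24),
            3 * sqrt(exp_ge24 * (1 - exp_ge24) / 600))
  # first visit is never dropped
  expect_true(all(tapply(coh$age_months, coh$child_id, min) < 1))
})

test_that("zero random-effects covariance gives identical parameters", {
  m <- ou_model(1, -0.5, 0.6)
  m$random_effect_names <- c("a2", "s")
  d <- cohort_design(5, sites = "A",
                     random_effects_cov = c(a2 = 0, s = 0), seed = 10)
  coh <- simulate_cohort(m, d)
  re <- attr(coh, "random_effects")
  expect_true(all(vapply(re, function(b) all(b == 0), logical(1))))
})

test_that("site offsets flow into the generated dynamics", {
  m <- sde_model(0, TRUE, c(a1 = -1.5, a2 = -3, s = 0.3),
                 site_offsets = list(a2 = c(Lo = 0, Hi = 4.5)))
  d <- cohort_design(30, sites = c("Lo", "Hi"), seed = 12,
                     init_mean = c(Lo = -2, Hi = 1), init_sd = 0.3)
  coh <- simulate_cohort(m, d)
  late <- coh[coh$age_months > 12, ]
  # stationary means -2 and +1
  expect_lt(abs(mean(late$zwfl[late$site == "Lo"]) - (-2)), 0.2)
  expect_lt(abs(mean(late$zwfl[late$site == "Hi"]) - 1), 0.2)
})
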