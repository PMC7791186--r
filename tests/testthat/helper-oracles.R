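# Independent closed-form oracles, transcribed directly from the published
# exponential expressions (not from the package's phi-function
# implementation), plus small fixture builders.

# OU transition law: mean e^{(t0-t1)a}(x0-b)+b,
# variance e^{-2 t1 a}(e^{2 t1 a} - e^{2 t0 a}) s^2 / (2a)
ou_slice_printed <- function(alpha, beta, sigma, x0, t0, t1) {
  list(mean = exp((t0 - t1) * alpha) * (x0 - beta) + beta,
       var = exp(-2 * t1 * alpha) * (exp(2 * t1 * alpha) -
                                       exp(2 * t0 * alpha)) *
         sigma^2 / (2 * alpha))
}

# cubic-drift transition law, direct transcription of the printed
# closed form (a = c(a1..a5); requires a1 != 0)
poly_slice_printed <- function(a, s, x0, t0, t1) {
  a1 <- a[1]; a2 <- a[2]; a3 <- a[3]; a4 <- a[4]; a5 <- a[5]
  E0 <- exp(t0 * a1); E1 <- exp(t1 * a1)
  mean <- exp(-t0 * a1) / a1^4 * (
    E1 * x0 * a1^4 -
      6 * (E0 - E1) * a5 +
      a1 * (-2 * (E0 - E1) * a4 - 6 * (-E1 * t0 + E0 * t1) * a5) +
      a1^2 * ((-E0 + E1) * a3 + 2 * E1 * t0 * a4 + 3 * E1 * t0^2 * a5 -
                E0 * t1 * (2 * a4 + 3 * t1 * a5)) +
      a1^3 * ((-E0 + E1) * a2 + E1 * t0 * a3 + E1 * t0^2 * a4 +
                E1 * t0^3 * a5 - E0 * t1 * (a3 + t1 * (a4 + t1 * a5))))
  var <- (-1 + exp(2 * (-t0 + t1) * a1)) * s^2 / (2 * a1)
  list(mean = mean, var = var)
}

random_cubic_model <- function() {
  sde_model(drift_order = 3L, mean_reversion = TRUE,
            params = c(a1 = runif(1, -1.2, -0.2),
                       a2 = runif(1, -0.5, 0.5),
                       a3 = runif(1, -0.05, 0.05),
                       a4 = runif(1, -0.01, 0.01),
                       a5 = runif(1, -5e-4, 5e-4),
                       s = runif(1, 0.4, 1)))
}

random_ou_model <- function() {
  ou_model(alpha = runif(1, 0.3, 1.5), beta = runif(1, -2, 1),
           sigma = runif(1, 0.4, 1))
}

# small single-site OU cohort for fitting tests
small_ou_cohort <- function(n = 40, alpha = 1.2, beta = -0.8, sigma = 0.6,
                            visits = 0:20, seed = 42,
                            re_cov = NULL, re_on = NULL, ...) {
  m <- ou_model(alpha, beta, sigma)
  if (!is.null(re_on)) m$random_effect_names <- re_on
  d <- cohort_design(n, sites = "A", visit_ages = visits,
                     random_effects_cov = re_cov, seed = seed, ...)
  simulate_cohort(m, d)
}

# model-implied mean path stepping by the slice mean (prediction oracle)
mean_path <- function(model, x0, t0, horizon, step, site = NULL) {
  t <- t0; x <- x0
  ages <- t; values <- x
  while (t < horizon - 1e-9) {
    dt <- min(step, horizon - t)
    x <- slice_density(model, x, t, t + dt, site)$mean
    t <- t + dt
    ages <- c(ages, t); values <- c(values, x)
  }
  data.frame(age = ages, predicted_value = values)
}
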