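# Exponential-integrator phi functions, the numerical backbone of the
# closed-form slice densities:
#
#   phi_k(z) = int_0^1 exp(z * (1 - w)) * w^(k-1) / (k-1)! dw
#            = sum_{n >= 0} z^n / (n + k)!
#
# so that  int_0^Delta exp(a * (Delta - v)) * v^j dv = j! * Delta^(j+1) *
# phi_{j+1}(a * Delta).  A Taylor series is used for small |z| (the upward
# recurrence phi_{k+1} = (phi_k - 1/k!) / z cancels catastrophically there),
# the recurrence otherwise.  Everything is vectorised over z.

PHI_SERIES_CUTOFF <- 0.9

phi_series_one <- function(z, k, nterms = 20L) {
  term <- 1 / factorial(k)
  acc <- term
  for (n in seq_len(nterms)) {
    term <- term * z / (n + k)
    acc <- acc + term
  }
  acc
}

# phi_k(z) for k = 1..kmax; returns a length(z) x kmax matrix
phi_funs <- function(z, kmax = 4L) {
  z <- as.numeric(z)
  out <- matrix(NA_real_, length(z), kmax)
  small <- abs(z) < PHI_SERIES_CUTOFF
  if (any(small)) {
    zs <- z[small]
    for (k in seq_len(kmax)) out[small, k] <- phi_series_one(zs, k)
  }
  if (any(!small)) {
    zl <- z[!small]
    p <- expm1(zl) / zl
    out[!small, 1L] <- p
    if (kmax >= 2L) {
      for (k in 2:kmax) {
        p <- (p - 1 / factorial(k - 1)) / zl
        out[!small, k] <- p
      }
    }
  }
  out
}
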