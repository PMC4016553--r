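# Reference scenario used across the suite.
paper_scenario <- function(...) hcc_scenario(...)

# Closed-form oracles, independent of the package's quadrature path.
# Transplanted survivors (unbiased policy):
#   F e^(-a0 T) * lam/(lam + d2 T) * (1 - e^(-(lam + d2 T) s0))
closed_ts <- function(scn, s0) {
  k <- scn$lambda + scn$delta2 * scn$T
  scn$F * exp(-scn$alpha0 * scn$T) * scn$lambda / k * (1 - exp(-k * s0))
}

# int_a^b lam e^(-lam s) exp(-a0 (a1 - e^(-d1 s)) T) ds in the special case
# lam == d1 (substitution u = e^(-d1 s) makes the integrand elementary).
closed_nt_integral <- function(scn, a, b) {
  stopifnot(abs(scn$lambda - scn$delta1) < 1e-12)
  ua <- exp(-scn$lambda * a)
  ub <- if (is.finite(b)) exp(-scn$lambda * b) else 0
  k <- scn$alpha0 * scn$T
  exp(-scn$alpha0 * scn$alpha1 * scn$T) * (exp(k * ua) - exp(k * ub)) / k
}

# Total mortality by closed forms (requires lam == d1, unbiased policy).
closed_m <- function(scn, s0) {
  nts <- scn$N * (1 - scn$F / scn$N) * closed_nt_integral(scn, 0, s0) +
    scn$N * closed_nt_integral(scn, s0, Inf)
  scn$N - closed_ts(scn, s0) - nts
}

# A feasible random scenario whose hazards cross at a known size:
# draw the crossing, then calibrate delta1 to it.
random_crossing_scenario <- function() {
  a0 <- stats::runif(1, 0.03, 0.10)
  d2 <- stats::runif(1, 0.002, 0.008)
  s_star <- stats::runif(1, 2, min(12, 0.9 * a0 / d2))
  base <- hcc_scenario(alpha0 = a0, delta2 = d2, delta1 = 1)  # placeholder d1
  d1 <- calibrate_delta1(s_star, base)
  list(scn = hcc_scenario(alpha0 = a0, delta2 = d2, delta1 = d1,
                          lambda = stats::runif(1, 0.15, 0.5)),
       s_star = s_star)
}
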