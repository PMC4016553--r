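scn <- paper_scenario()

test_that("hazards reproduce the reference values and their limits", {
  expect_equal(hazard_nontransplanted(0, scn), 0.048)
  expect_equal(hazard_nontransplanted(5, scn), 0.048 * (2 - exp(-1.5)))
  expect_equal(hazard_nontransplanted(5, scn), 0.085290, tolerance = 1e-5)
  expect_equal(hazard_nontransplanted(1e6, scn), 2 * 0.048)  # saturates at a0*a1
  expect_equal(hazard_transplanted(0, scn), 0.048)
  expect_equal(hazard_transplanted(5, scn), 0.078)
  expect_equal(hazard_transplanted(10, scn), 0.108)
  expect_error(hazard_nontransplanted(-1, scn), "non-negative")
  expect_error(hazard_transplanted(c(2, -3), scn), "non-negative")
})

test_that("hazards coincide at s = 0 exactly when alpha1 = 2, for any alpha0", {
  for (a0 in c(0.01, 0.048, 0.3)) {
    s2 <- hcc_scenario(alpha0 = a0)
    expect_identical(hazard_nontransplanted(0, s2), hazard_transplanted(0, s2))
  }
})

test_that("non-transplanted hazard is concave increasing, transplanted convex increasing", {
  s <- seq(0, 20, by = 0.25)
  h_nt <- hazard_nontransplanted(s, scn)
  h_t <- hazard_transplanted(s, scn)
  expect_true(all(diff(h_nt) > 0))
  expect_true(all(diff(h_t) > 0))
  expect_true(all(diff(diff(h_nt)) < 0))        # concave
  expect_true(all(diff(diff(h_t)) > -1e-12))    # (weakly) convex
})

test_that("survival probabilities match direct evaluation and decrease in s and T", {
  expect_equal(survival_nontransplanted(0, scn), exp(-0.24))
  expect_equal(survival_nontransplanted(0, scn), 0.786628, tolerance = 1e-6)
  expect_equal(survival_nontransplanted(5, scn), 0.652824, tolerance = 1e-5)
  expect_equal(survival_transplanted(5, scn), exp(-0.39))
  expect_equal(survival_transplanted(5, scn), 0.677057, tolerance = 1e-6)
  expect_equal(survival_transplanted(0, scn), survival_nontransplanted(0, scn))
  scn0 <- hcc_scenario(T = 0)
  expect_equal(survival_nontransplanted(c(0, 3, 12), scn0), rep(1, 3))
  expect_equal(survival_transplanted(7, scn0), 1)

  s <- seq(0, 25, by = 0.5)
  for (f in list(survival_nontransplanted, survival_transplanted)) {
    v <- f(s, scn)
    expect_true(all(v > 0 & v <= 1))
    expect_true(all(diff(v) < 0))
    expect_true(all(f(s, hcc_scenario(T = 10)) < v))  # longer horizon, less survival
  }
})

test_that("size distribution has exponential density, CDF and moments", {
  expect_equal(size_pdf(0, 0.3), 0.3)
  expect_equal(size_pdf(5, 0.3), 0.3 * exp(-1.5))
  expect_equal(size_cdf(5, 0.3), 1 - exp(-1.5))
  expect_equal(size_cdf(0, 0.3), 0)
  expect_equal(size_cdf(1e9, 0.3), 1)
  expect_equal(unname(size_moments(0.3)), c(1 / 0.3, 1 / 0.09))
  expect_equal(round(size_moments(0.3)[["mean"]], 1), 3.3)
  expect_equal(unname(size_moments(1)), c(1, 1))
  expect_error(size_pdf(-0.5, 0.3), "non-negative")
  # normalization and CDF consistency with the integrated density
  expect_equal(integrate(size_pdf, 0, Inf, lambda = 0.3)$value, 1,
               tolerance = 1e-8)
  set.seed(11)
  for (s in runif(5, 0.2, 15)) {
    expect_equal(size_cdf(s, 0.3),
                 integrate(size_pdf, 0, s, lambda = 0.3)$value,
                 tolerance = 1e-8)
  }
})

test_that("crossing_size finds the positive hazard crossing or reports none", {
  expect_equal(crossing_size(scn), 7.028767, tolerance = 1e-5)
  s7 <- hcc_scenario(delta1 = log(8) / 7)
  expect_equal(crossing_size(s7), 7, tolerance = 1e-6)
  # slowly rising non-transplanted hazard: transplantation never wins at s > 0
  expect_true(is.na(crossing_size(hcc_scenario(delta1 = 0.02))))
})

test_that("calibrate_delta1 inverts crossing_size on feasible inputs", {
  expect_equal(calibrate_delta1(7, scn), log(8) / 7)
  expect_equal(calibrate_delta1(1e-9, scn), 0.006 / 0.048, tolerance = 1e-6)
  expect_error(calibrate_delta1(1000, scn), "feasible")
  set.seed(21)
  for (i in 1:10) {
    s_star <- runif(1, 0.5, 7.9)   # feasible range: s* < alpha0/delta2 = 8
    d1 <- calibrate_delta1(s_star, scn)
    scn2 <- hcc_scenario(delta1 = d1)
    expect_equal(crossing_size(scn2), s_star, tolerance = 1e-8)
  }
})

test_that("scenario constructor validates parameters and names the offender", {
  expect_error(hcc_scenario(alpha0 = -1), "alpha0")
  expect_error(hcc_scenario(delta1 = 0.004, delta2 = 0.006), "delta1")
  expect_error(hcc_scenario(F = 1500), "F")
  expect_error(hcc_scenario(F = 2000), "F")
  expect_error(hcc_scenario(lambda = 0), "lambda")
  expect_error(hcc_scenario(g = function(s) s * 10), "\\[0, 1\\]")
  expect_s3_class(hcc_scenario(s0 = Inf), "hcc_scenario")
})
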