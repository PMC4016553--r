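scn <- paper_scenario()

test_that("transplanted survivors: quadrature agrees with the closed form", {
  for (s0 in c(0, 1, 5, 7.03, 10, Inf)) {
    expect_equal(transplanted_survivors(scn, s0), closed_ts(scn, s0),
                 tolerance = 1e-8)
  }
  expect_equal(transplanted_survivors(scn, Inf),
               500 * exp(-0.24) * 0.3 / 0.33, tolerance = 1e-8)
  expect_equal(transplanted_survivors(scn, Inf), 357.558, tolerance = 1e-5)
  expect_equal(transplanted_survivors(scn, 0), 0)
  # zero horizon: every transplanted patient is alive, so TS = grafts used
  scn0 <- hcc_scenario(T = 0)
  for (s0 in c(2, 5, 10)) {
    expect_equal(transplanted_survivors(scn0, s0), grafts_used(scn0, s0),
                 tolerance = 1e-8)
  }
})

test_that("non-transplanted survivors match the analytic special cases", {
  # s0 = 0: nobody transplanted; with lambda = delta1 the integral is elementary
  expect_equal(nontransplanted_survivors(scn, 0),
               scn$N * closed_nt_integral(scn, 0, Inf), tolerance = 1e-8)
  expect_equal(nontransplanted_survivors(scn, 0), 1049.03, tolerance = 1e-5)
  expect_equal(nontransplanted_survivors(scn, 0),
               1500 * exp(-0.48) * (exp(0.24) - 1) / 0.24, tolerance = 1e-8)
  # zero horizon: everyone not transplanted is alive
  scn0 <- hcc_scenario(T = 0)
  for (s0 in c(0, 3, 8)) {
    expect_equal(nontransplanted_survivors(scn0, s0),
                 scn0$N - grafts_used(scn0, s0), tolerance = 1e-8)
  }
  # null policy: threshold is irrelevant when nobody can be transplanted
  scnn <- hcc_scenario(g = policy_bias("constant", value = 0))
  base <- nontransplanted_survivors(scnn, 0)
  for (s0 in c(2, 6, 14)) {
    expect_equal(nontransplanted_survivors(scnn, s0), base, tolerance = 1e-10)
  }
})

test_that("total mortality reproduces the closed-form endpoints", {
  expect_equal(total_mortality(scn, 0), closed_m(scn, 0), tolerance = 1e-8)
  expect_equal(total_mortality(scn, 0), 450.97, tolerance = 1e-4)
  expect_equal(total_mortality(scn, Inf), closed_m(scn, Inf), tolerance = 1e-8)
  expect_equal(total_mortality(scn, Inf), 443.09, tolerance = 1e-4)
  expect_equal(total_mortality(hcc_scenario(T = 0), 5), 0, tolerance = 1e-9)
  # closed form agrees all along the curve, not just at the ends
  for (s0 in c(2, 5, 7, 10, 13)) {
    expect_equal(total_mortality(scn, s0), closed_m(scn, s0), tolerance = 1e-8)
  }
})

test_that("survivors and deaths always partition the cohort", {
  grids <- list(seq(0, 15, by = 0.5),
                c(0.1, 1.35, 5, 7.03, 12))
  scns <- list(scn, hcc_scenario(delta1 = 0.02, T = 3),
               hcc_scenario(s0 = 8, g = policy_bias("step", at = 4)))
  for (s2 in scns) {
    for (g in grids) {
      tot <- vapply(g, function(s0) {
        total_survivors(s2, s0) + total_mortality(s2, s0)
      }, 0)
      expect_equal(tot, rep(s2$N, length(g)), tolerance = 1e-9)
    }
  }
})

test_that("mortality curve falls to a minimum near 7 cm and rises again", {
  crv <- mortality_curve(scn, seq(0, 15, by = 0.01))
  expect_s3_class(crv, "mortality_curve")
  expect_equal(nrow(crv), 1501L)
  expect_true(all(crv$deaths >= 0 & crv$deaths <= scn$N))
  expect_true(all(crv$grafts_used <= scn$F))
  expect_equal(crv$deaths + crv$survivors, rep(scn$N, nrow(crv)),
               tolerance = 1e-9)
  dec <- crv$s0 >= 5 & crv$s0 <= 7
  inc <- crv$s0 >= 7.1
  expect_true(all(diff(crv$deaths[dec]) < 0))
  expect_true(all(diff(crv$deaths[inc]) > 0))
  m5 <- crv$deaths[which.min(abs(crv$s0 - 5))]
  m6 <- crv$deaths[which.min(abs(crv$s0 - 6))]
  expect_lt(m6, m5)
  expect_error(mortality_curve(scn, numeric(0)), "non-empty")
})

test_that("optimal threshold sits at the hazard crossing (stationarity identity)", {
  opt <- optimal_threshold(scn)
  expect_false(opt$boundary)
  expect_equal(opt$s_star, crossing_size(scn), tolerance = 1e-4)
  expect_equal(round(opt$s_star), 7)
  # calibrated variant: crossing placed exactly at 7
  s7 <- hcc_scenario(delta1 = log(8) / 7)
  expect_equal(optimal_threshold(s7)$s_star, 7, tolerance = 0.01)
  # hazards that never cross: transplantation is always harmful, boundary optimum
  flat <- optimal_threshold(hcc_scenario(delta1 = 0.02))
  expect_true(flat$boundary)
  expect_equal(flat$s_star, 0)
  # randomized feasible scenarios with a known constructed crossing
  set.seed(31)
  for (i in 1:6) {
    rc <- random_crossing_scenario()
    opt_i <- optimal_threshold(rc$scn)
    expect_equal(opt_i$s_star, rc$s_star, tolerance = 0.05)
    expect_equal(opt_i$s_star, crossing_size(rc$scn), tolerance = 0.05)
  }
})

test_that("transplantation up to s0 helps exactly when the hazard gap favors it", {
  # M(s0) - M(0) = -F int_0^s0 lam e^(-lam s) (pi_t - pi_nt) ds
  set.seed(41)
  for (i in 1:5) {
    rc <- random_crossing_scenario()
    s2 <- rc$scn
    for (s0 in runif(3, 0.5, 14)) {
      gap <- integrate(function(s) {
        size_pdf(s, s2$lambda) *
          (survival_transplanted(s, s2) - survival_nontransplanted(s, s2))
      }, 0, s0, rel.tol = 1e-10)$value
      diffM <- total_mortality(s2, s0) - total_mortality(s2, 0)
      expect_equal(diffM, -s2$F * gap, tolerance = 1e-6)
    }
  }
})

test_that("equivalent threshold returns mortality to the Milan level near 10 cm", {
  eq <- equivalent_threshold(scn)
  expect_gt(eq$s_eq, eq$s_star)
  expect_equal(round(eq$s_eq), 10)
  expect_lt(abs(eq$M_eq - eq$M_ref), 1e-6 * scn$N)
  expect_equal(eq$M_ref, total_mortality(scn, 5))
  # no interior minimum beyond the cutoff: reported as undefined, with a reason
  none <- equivalent_threshold(hcc_scenario(delta1 = 0.02))
  expect_true(is.na(none$s_eq))
  expect_match(none$reason, "minimum")
})
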