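# Quadrature over the size distribution: int_a^b lambda e^(-lambda s) f(s) ds.
# The infinite tail is mapped to a finite interval with u = exp(-lambda s)
# (du = -lambda e^(-lambda s) ds), so no arbitrary truncation is involved.
# Absolute tolerance 1e-10 on proportions.
quad_size <- function(f, lower, upper, lambda, tol = 1e-10) {
  if (upper <= lower) return(0)
  if (is.finite(upper)) {
    stats::integrate(function(s) lambda * exp(-lambda * s) * f(s),
                     lower, upper, rel.tol = tol, abs.tol = tol,
                     subdivisions = 200L)$value
  } else {
    u_hi <- exp(-lambda * lower)
    if (u_hi == 0) return(0)
    stats::integrate(function(u) f(-log(u) / lambda),
                     0, u_hi, rel.tol = tol, abs.tol = tol,
                     subdivisions = 200L)$value
  }
}

#' Expected survivors after the horizon, by transplantation status
#'
#' Expected counts of patients alive at the end of the horizon `T` under the
#' threshold policy `s0`, obtained by adaptive quadrature of the survival
#' integrals over the exponential size distribution:
#' \deqn{TS(s_0) = N\int_0^{s_0} g(s)\tfrac{F}{N}\,\lambda e^{-\lambda s}
#'   e^{-\alpha_t(s)T}\,ds}
#' for the transplanted, and for the non-transplanted
#' \deqn{NTS(s_0) = N\int_0^{s_0}\big(1 - g(s)\tfrac{F}{N}\big)\lambda
#'   e^{-\lambda s} e^{-\alpha_{nt}(s)T}\,ds +
#'   N\int_{s_0}^{\infty}\lambda e^{-\lambda s} e^{-\alpha_{nt}(s)T}\,ds.}
#' The infinite tail is computed exactly on the transformed variable
#' \eqn{u = e^{-\lambda s}}. For the unbiased policy the transplanted
#' integral has the closed form
#' \eqn{F e^{-\alpha_0 T}\frac{\lambda}{\lambda + \delta_2 T}
#' (1 - e^{-(\lambda+\delta_2 T)s_0})}, used as a cross-check in the test
#' suite.
#'
#' @param scn An [hcc_scenario()].
#' @param s0 Transplantation threshold in cm (may be `Inf`); defaults to the
#'   scenario's own.
#' @return Expected patient count (real-valued).
#' @examples
#' scn <- hcc_scenario()
#' transplanted_survivors(scn, s0 = Inf)
#' nontransplanted_survivors(scn, s0 = 0)
#' @export
transplanted_survivors <- function(scn, s0 = scn$s0) {
  check_sizes(s0)
  frac <- scn$F / scn$N
  quad_size(function(s) bias_at(scn, s) * frac * survival_transplanted(s, scn),
            0, s0, scn$lambda) * scn$N
}

#' @rdname transplanted_survivors
#' @export
nontransplanted_survivors <- function(scn, s0 = scn$s0) {
  check_sizes(s0)
  frac <- scn$F / scn$N
  below <- quad_size(function(s)
    (1 - bias_at(scn, s) * frac) * survival_nontransplanted(s, scn),
    0, s0, scn$lambda)
  above <- quad_size(function(s) survival_nontransplanted(s, scn),
                     s0, Inf, scn$lambda)
  scn$N * (below + above)
}

#' @rdname transplanted_survivors
#' @export
total_survivors <- function(scn, s0 = scn$s0) {
  transplanted_survivors(scn, s0) + nontransplanted_survivors(scn, s0)
}

#' Total expected mortality under a threshold policy
#'
#' `M(s0) = N - total_survivors(s0)`: expected deaths over the horizon among
#' transplanted and non-transplanted patients combined, as a function of the
#' transplantation size threshold. Its derivative in `s0` is
#' \eqn{-F\lambda e^{-\lambda s_0} g(s_0)\,[e^{-\alpha_t(s_0)T} -
#' e^{-\alpha_{nt}(s_0)T}]}, so `M` is stationary exactly where the two
#' hazards cross ([crossing_size()]).
#'
#' @inheritParams transplanted_survivors
#' @return Expected death count.
#' @examples
#' total_mortality(hcc_scenario(), s0 = 7)
#' @export
total_mortality <- function(scn, s0 = scn$s0) {
  scn$N - total_survivors(scn, s0)
}

#' Mortality as a function of the transplantation threshold
#'
#' Evaluates total mortality, survivors and expected grafts used on an
#' ordered grid of candidate thresholds.
#'
#' @param scn An [hcc_scenario()].
#' @param thresholds Ordered non-negative grid of thresholds, cm. The default
#'   0.01 cm grid over \[0, 15\] resolves the optimum to the grid step in
#'   well under a second.
#' @return A data frame of class `"mortality_curve"` with columns `s0`,
#'   `deaths`, `survivors`, `grafts_used`, and the full parameter record in
#'   `attr(, "params")`.
#' @examples
#' crv <- mortality_curve(hcc_scenario(), thresholds = seq(0, 15, 0.5))
#' crv
#' @export
mortality_curve <- function(scn, thresholds = seq(0, 15, by = 0.01)) {
  if (!length(thresholds)) stop("'thresholds' must be non-empty", call. = FALSE)
  check_sizes(thresholds)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("'thresholds' must be strictly increasing", call. = FALSE)
  surv <- vapply(thresholds, function(s0) total_survivors(scn, s0), 0)
  out <- data.frame(s0 = thresholds,
                    deaths = scn$N - surv,
                    survivors = surv,
                    grafts_used = grafts_used(scn, thresholds))
  attr(out, "params") <- scenario_record(scn)
  class(out) <- c("mortality_curve", class(out))
  out
}

#' @export
print.mortality_curve <- function(x, ...) {
  i <- which.min(x$deaths)
  cat(sprintf("Mortality curve: %d thresholds in [%g, %g] cm\n",
              nrow(x), min(x$s0), max(x$s0)))
  cat(sprintf("  minimum %.2f deaths at s0 = %g cm\n", x$deaths[i], x$s0[i]))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("  ... %d more rows\n", nrow(x) - 4L))
  invisible(x)
}

#' Plot a mortality curve
#'
#' Deaths against the transplantation threshold, with the Milan-cutoff
#' mortality drawn as a horizontal reference line; where the curve re-crosses
#' that line is the largest threshold that does not worsen list mortality.
#'
#' @param x A [mortality_curve()].
#' @param reference Threshold for the reference line, cm (default: the
#'   scenario's Milan cutoff); `NA` suppresses it.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mortality_curve <- function(x, reference = attr(x, "params")[["S_M"]],
                                 ...) {
  graphics::plot(x$s0, x$deaths, type = "l",
                 xlab = "transplantation threshold s0 (cm)",
                 ylab = sprintf("total deaths by T = %g yr",
                                attr(x, "params")[["T"]]), ...)
  if (!is.na(reference)) {
    ref <- x$deaths[which.min(abs(x$s0 - reference))]
    graphics::abline(h = ref, lty = 3)
  }
  invisible(x)
}

#' Threshold minimizing total mortality
#'
#' Coarse grid search followed by golden-section refinement of `M(s0)`. A
#' minimum on the lower boundary (`s0 = 0`: transplantation never helps) is
#' reported as such rather than refined; ties go to the smallest threshold.
#' For the unbiased policy the interior optimum coincides with the
#' hazard-crossing size.
#'
#' @param scn An [hcc_scenario()].
#' @param thresholds Search grid, cm (default 0.01 cm steps on \[0, 15\]).
#' @return A list: `s_star` (cm), `M_star` (deaths), `boundary` (`TRUE` when
#'   the minimum sits on the grid boundary).
#' @examples
#' optimal_threshold(hcc_scenario())  # s_star about 7.03
#' @export
optimal_threshold <- function(scn, thresholds = seq(0, 15, by = 0.01)) {
  crv <- mortality_curve(scn, thresholds)
  i <- which.min(crv$deaths)
  step <- if (nrow(crv) > 1L) max(diff(crv$s0)) else 0.01
  if (i == 1L || i == nrow(crv)) {
    return(list(s_star = crv$s0[i], M_star = crv$deaths[i], boundary = TRUE))
  }
  ref <- stats::optimize(function(s0) total_mortality(scn, s0),
                         lower = crv$s0[i] - step, upper = crv$s0[i] + step,
                         tol = 1e-8)
  list(s_star = ref$minimum, M_star = ref$objective, boundary = FALSE)
}

#' Largest threshold with mortality no worse than the Milan cutoff
#'
#' Past its interior minimum, `M(s0)` rises again; the equivalent threshold
#' `s_eq` is the size beyond the optimum at which mortality climbs back to
#' its value at the Milan cutoff, `M(s_eq) = M(S_M)` — the maximum expansion
#' of the transplantation criteria that does not worsen list mortality. The
#' root is bracketed on `[s_star, s_hi]` with `s_hi` grown geometrically up
#' to the `1 - 1e-10` quantile of the size distribution.
#'
#' @param scn An [hcc_scenario()].
#' @return A list: `s_eq` (cm, `NA` with a `reason` when undefined), `M_eq`,
#'   `M_ref` (= `M(S_M)`), `s_star`.
#' @examples
#' equivalent_threshold(hcc_scenario())  # s_eq about 10.3, rounds to 10
#' @export
equivalent_threshold <- function(scn) {
  opt <- optimal_threshold(scn)
  M_ref <- total_mortality(scn, scn$S_M)
  out <- list(s_eq = NA_real_, M_eq = NA_real_, M_ref = M_ref,
              s_star = opt$s_star)
  if (opt$boundary || opt$s_star <= scn$S_M) {
    out$reason <- "no interior minimum beyond the Milan cutoff"
    return(out)
  }
  h <- function(s) total_mortality(scn, s) - M_ref
  s_max <- stats::qexp(1 - 1e-10, rate = scn$lambda)
  s_hi <- max(2 * opt$s_star, scn$S_M + 1)
  while (h(s_hi) < 0 && s_hi < s_max) s_hi <- min(2 * s_hi, s_max)
  if (h(s_hi) < 0) {
    out$reason <- sprintf(
      "M(s0) never returns to M(S_M) = %.4f below the %.1f cm size quantile",
      M_ref, s_max)
    return(out)
  }
  root <- stats::uniroot(h, c(opt$s_star, s_hi), tol = 1e-9)$root
  out$s_eq <- root
  out$M_eq <- total_mortality(scn, root)
  out$reason <- NULL
  out
}
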