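#' Construct an allocation scenario
#'
#' Bundles every parameter of the waiting-list model into a validated object:
#' the mortality-hazard parameters, the exponential tumor-size distribution,
#' the cohort (waiting-list size and graft supply), and the allocation policy
#' (size threshold plus optional size-bias function).
#'
#' The two hazards are
#' \deqn{\alpha_{nt}(s) = \alpha_0(\alpha_1 - e^{-\delta_1 s}), \qquad
#'       \alpha_t(s) = \alpha_0 + \delta_2 s,}
#' both in deaths per patient-year, with \eqn{s} the tumor size (cm) at
#' presentation. With `alpha1 = 2` the two hazards coincide at `s = 0`, so an
#' untreated patient with a vanishing tumor faces the same risk as a
#' transplanted one; the model keeps that convention by default. Tumor size is
#' exponential with rate `lambda` (per cm). Survival over the horizon `T`
#' (years) is `exp(-hazard * T)`: hazards are constant in time at fixed size.
#'
#' The default parameter set is the reference scenario used throughout the
#' package: `alpha0 = 0.048`, `alpha1 = 2`, `delta1 = 0.3`, `delta2 = 0.006`,
#' `lambda = 0.3`, `T = 5`, `N = 1500`, `F = 500`, `S_M = 5`.
#'
#' @param alpha0 Baseline mortality rate, per year. Strictly positive.
#' @param alpha1 Dimensionless multiplier of the non-transplanted hazard.
#'   `alpha1 = 2` is the unique value equating the two hazards at `s = 0`.
#' @param delta1 Shape rate of the non-transplanted hazard, per cm. Must
#'   exceed `delta2`.
#' @param delta2 Slope of the transplanted hazard, per year per cm.
#' @param lambda Rate of the exponential tumor-size distribution, per cm.
#' @param T Survival horizon in years (non-negative).
#' @param N Number of patients on the waiting list.
#' @param F Number of available liver grafts; must satisfy `0 < F < N`.
#' @param S_M Milan size cutoff in cm (default 5).
#' @param s0 Transplantation size threshold of the policy, cm. Defaults to
#'   `S_M` (the Milan policy); may be `Inf` (transplant proportionally at
#'   every size).
#' @param g Optional size-bias function on `[0, Inf)` with values in
#'   `[0, 1]`; `NULL` means the unbiased policy `g(s) = 1` (every eligible
#'   patient has the same transplantation chance `F/N`). See [policy_bias()].
#'
#' @return An object of class `"hcc_scenario"`: a named list of the validated
#'   parameters with the bias function stored in `$g` (`NULL` for unbiased).
#'
#' @examples
#' scn <- hcc_scenario()
#' scn
#' total_mortality(scn, s0 = 7)
#' @seealso [mortality_curve()], [optimal_threshold()], [milan_summary()],
#'   [simulate.hcc_scenario()]
#' @export
hcc_scenario <- function(alpha0 = 0.048, alpha1 = 2, delta1 = 0.3,
                         delta2 = 0.006, lambda = 0.3, T = 5,
                         N = 1500, F = 500, S_M = 5,
                         s0 = S_M, g = NULL) {
  num1 <- function(x, key) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
      stop(sprintf("'%s' must be a single non-missing number", key),
           call. = FALSE)
    as.numeric(x)
  }
  alpha0 <- num1(alpha0, "alpha0"); alpha1 <- num1(alpha1, "alpha1")
  delta1 <- num1(delta1, "delta1"); delta2 <- num1(delta2, "delta2")
  lambda <- num1(lambda, "lambda"); T <- num1(T, "T")
  N <- num1(N, "N"); F <- num1(F, "F"); S_M <- num1(S_M, "S_M")
  s0 <- num1(s0, "s0")

  for (key in c("alpha0", "alpha1", "delta1", "delta2", "lambda")) {
    if (get(key) <= 0)
      stop(sprintf("'%s' must be strictly positive", key), call. = FALSE)
  }
  if (T < 0) stop("'T' must be non-negative", call. = FALSE)
  if (delta1 <= delta2)
    stop("'delta1' must exceed 'delta2' (non-transplanted hazard must rise ",
         "faster in size than the transplanted one)", call. = FALSE)
  if (N <= 0) stop("'N' must be strictly positive", call. = FALSE)
  if (F <= 0 || F >= N)
    stop("'F' must satisfy 0 < F < N: graft supply is limited and below ",
         "demand", call. = FALSE)
  if (S_M <= 0) stop("'S_M' must be strictly positive", call. = FALSE)
  if (s0 < 0) stop("'s0' must be non-negative", call. = FALSE)
  if (!is.null(g)) {
    if (!is.function(g)) stop("'g' must be a function or NULL", call. = FALSE)
    probe <- g(c(0, 1, S_M, 2 * S_M))
    if (any(!is.finite(probe)) || any(probe < 0) || any(probe > 1))
      stop("'g' must map sizes to [0, 1]", call. = FALSE)
  }

  structure(
    list(alpha0 = alpha0, alpha1 = alpha1, delta1 = delta1, delta2 = delta2,
         lambda = lambda, T = T, N = N, F = F, S_M = S_M, s0 = s0, g = g),
    class = "hcc_scenario")
}

#' Size-bias policy functions
#'
#' Builds the bias function `g(s)` of an allocation policy from a config-style
#' description. Within the eligible range `s <= s0`, a patient of size `s` is
#' transplanted with probability `g(s) * F/N`.
#'
#' @param type `"constant"` (value `value` everywhere), `"step"` (`1` for
#'   `s <= at`, `0` above — the Milan rule is `step` at `S_M`), or `"table"`
#'   (linear interpolation through `(breaks, values)`, constant beyond the
#'   range).
#' @param value Constant bias in `[0, 1]` (type `"constant"`).
#' @param at Step location in cm (type `"step"`).
#' @param breaks,values Breakpoints (cm) and bias values in `[0, 1]`
#'   (type `"table"`).
#' @return A vectorized function of size with values in `[0, 1]`.
#' @examples
#' g <- policy_bias("step", at = 5)
#' g(c(3, 7))
#' @export
policy_bias <- function(type = c("constant", "step", "table"),
                        value = 1, at = 5, breaks = NULL, values = NULL) {
  type <- match.arg(type)
  switch(type,
    constant = {
      stopifnot(value >= 0, value <= 1)
      function(s) rep_len(value, length(s))
    },
    step = {
      stopifnot(at >= 0)
      function(s) as.numeric(s <= at)
    },
    table = {
      if (is.null(breaks) || is.null(values) ||
          length(breaks) != length(values) || length(breaks) < 2L)
        stop("'table' bias needs matching 'breaks' and 'values' (>= 2 points)")
      if (any(values < 0) || any(values > 1))
        stop("'values' must lie in [0, 1]")
      function(s) stats::approx(breaks, values, xout = s, rule = 2)$y
    })
}

# Effective bias: identity 1 when no g is set.
bias_at <- function(scn, s) {
  if (is.null(scn$g)) rep_len(1, length(s)) else scn$g(s)
}

#' @export
print.hcc_scenario <- function(x, ...) {
  cat("Liver-allocation scenario (hcc_scenario)\n")
  cat(sprintf("  hazards : alpha0=%g /yr, alpha1=%g, delta1=%g /cm, delta2=%g /yr/cm\n",
              x$alpha0, x$alpha1, x$delta1, x$delta2))
  cat(sprintf("  sizes   : exponential, lambda=%g /cm (mean %.2f cm)\n",
              x$lambda, 1 / x$lambda))
  cat(sprintf("  cohort  : N=%g patients, F=%g grafts, horizon T=%g yr\n",
              x$N, x$F, x$T))
  cat(sprintf("  policy  : threshold s0=%g cm (Milan cutoff S_M=%g cm), bias %s\n",
              x$s0, x$S_M, if (is.null(x$g)) "none (g=1)" else "custom g(s)"))
  invisible(x)
}

#' Summarize an allocation scenario
#'
#' Evaluates the scenario's headline quantities at its own threshold `s0`:
#' expected 5-year (or horizon-`T`) deaths and survivors, grafts used, the
#' full-utilization threshold, the hazard-crossing size and the optimal
#' threshold.
#'
#' @param object An `hcc_scenario`.
#' @param ... Unused.
#' @return A named list of class `"summary.hcc_scenario"`.
#' @export
summary.hcc_scenario <- function(object, ...) {
  opt <- optimal_threshold(object)
  out <- list(
    scenario = object,
    deaths = total_mortality(object),
    survivors = total_survivors(object),
    grafts_used = grafts_used(object),
    full_utilization = full_utilization_threshold(object),
    crossing = crossing_size(object),
    s_star = opt$s_star,
    M_star = opt$M_star)
  class(out) <- "summary.hcc_scenario"
  out
}

#' @export
print.summary.hcc_scenario <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("  at s0=%g cm: %.2f expected deaths, %.2f survivors, %.1f grafts used\n",
              x$scenario$s0, x$deaths, x$survivors, x$grafts_used))
  cat(sprintf("  full-utilization threshold s_F = %.3f cm\n", x$full_utilization))
  cat(sprintf("  hazard crossing at %s cm; optimal threshold s* = %.2f cm (M = %.2f)\n",
              if (is.na(x$crossing)) "none" else sprintf("%.3f", x$crossing),
              x$s_star, x$M_star))
  invisible(x)
}

# Flat named vector of scalar parameters, echoed into output headers.
scenario_record <- function(scn) {
  c(alpha0 = scn$alpha0, alpha1 = scn$alpha1, delta1 = scn$delta1,
    delta2 = scn$delta2, lambda = scn$lambda, T = scn$T,
    N = scn$N, F = scn$F, S_M = scn$S_M, s0 = scn$s0)
}
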