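#' Size-dependent mortality hazards
#'
#' Instantaneous mortality rates (per year) as a function of tumor size at
#' presentation. Non-transplanted patients follow the saturating form
#' \eqn{\alpha_{nt}(s) = \alpha_0(\alpha_1 - e^{-\delta_1 s})} — concave,
#' increasing, bounded by \eqn{\alpha_0\alpha_1}. Transplanted patients follow
#' the linear form \eqn{\alpha_t(s) = \alpha_0 + \delta_2 s}. With
#' \eqn{\alpha_1 = 2} the two coincide at \eqn{s = 0} and, provided
#' \eqn{\alpha_0\delta_1 > \delta_2}, cross once more at a positive size:
#' below the crossing transplantation lowers the hazard, above it it does not.
#'
#' @param s Tumor size(s) in cm, non-negative.
#' @param scn An [hcc_scenario()].
#' @return Mortality rate(s), per year.
#' @examples
#' scn <- hcc_scenario()
#' hazard_nontransplanted(5, scn)
#' hazard_transplanted(5, scn)
#' @export
hazard_nontransplanted <- function(s, scn) {
  check_sizes(s)
  scn$alpha0 * (scn$alpha1 - exp(-scn$delta1 * s))
}

#' @rdname hazard_nontransplanted
#' @export
hazard_transplanted <- function(s, scn) {
  check_sizes(s)
  scn$alpha0 + scn$delta2 * s
}

#' Survival probabilities over the horizon
#'
#' Probability of surviving the scenario horizon `T` years at fixed tumor
#' size: `exp(-hazard(s) * T)` for the respective hazard (constant-in-time
#' hazard at fixed size).
#'
#' @inheritParams hazard_nontransplanted
#' @return Survival probabilities in `(0, 1]`.
#' @examples
#' scn <- hcc_scenario()
#' survival_transplanted(5, scn)
#' @export
survival_nontransplanted <- function(s, scn) {
  exp(-hazard_nontransplanted(s, scn) * scn$T)
}

#' @rdname survival_nontransplanted
#' @export
survival_transplanted <- function(s, scn) {
  exp(-hazard_transplanted(s, scn) * scn$T)
}

#' Exponential tumor-size distribution
#'
#' Density, distribution function and first two moments of the exponential
#' size-at-presentation distribution with rate `lambda` (per cm): density
#' \eqn{\lambda e^{-\lambda s}}, CDF \eqn{1 - e^{-\lambda s}}, mean
#' \eqn{1/\lambda}, variance \eqn{1/\lambda^2}. Thin wrappers over
#' [stats::dexp()] / [stats::pexp()] that enforce the model's domain
#' (negative sizes are an error, not a silent zero).
#'
#' @param s Tumor size(s) in cm, non-negative.
#' @param lambda Rate parameter, per cm, strictly positive.
#' @return `size_pdf`: density per cm; `size_cdf`: probability;
#'   `size_moments`: named vector `c(mean, variance)` in cm and cm^2.
#' @examples
#' size_pdf(5, 0.3)
#' size_cdf(5, 0.3)
#' size_moments(0.3)
#' @export
size_pdf <- function(s, lambda) {
  check_sizes(s)
  stopifnot(lambda > 0)
  stats::dexp(s, rate = lambda)
}

#' @rdname size_pdf
#' @export
size_cdf <- function(s, lambda) {
  check_sizes(s)
  stopifnot(lambda > 0)
  stats::pexp(s, rate = lambda)
}

#' @rdname size_pdf
#' @export
size_moments <- function(lambda) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda > 0)
  c(mean = 1 / lambda, variance = 1 / lambda^2)
}

#' Size at which the two hazards cross
#'
#' Smallest strictly positive root of
#' \eqn{\alpha_{nt}(s) = \alpha_t(s)}. Below the crossing transplantation
#' reduces the mortality rate; above it, it increases it — so the crossing is
#' the stationary point of total mortality as a function of the policy
#' threshold. Returns `NA` when the hazards never meet at a positive size
#' (e.g. when the non-transplanted hazard rises too slowly:
#' \eqn{\alpha_0\delta_1 \le \delta_2} with \eqn{\alpha_1 = 2}).
#'
#' @param scn An [hcc_scenario()].
#' @param upper Upper end of the search interval, cm.
#' @return Crossing size in cm, or `NA_real_` when no positive crossing
#'   exists.
#' @examples
#' crossing_size(hcc_scenario())           # about 7.03 cm
#' crossing_size(hcc_scenario(delta1 = 0.02))  # NA: hazards never cross
#' @export
crossing_size <- function(scn, upper = 500) {
  f <- function(s) hazard_nontransplanted(s, scn) - hazard_transplanted(s, scn)
  # scan a geometric grid for the first sign change away from the s=0 root
  grid <- c(1e-9, exp(seq(log(1e-6), log(upper), length.out = 400L)))
  v <- f(grid)
  chg <- which(v[-1] * v[-length(v)] < 0)
  if (!length(chg)) return(NA_real_)
  i <- chg[1L]
  stats::uniroot(f, c(grid[i], grid[i + 1L]), tol = 1e-12)$root
}

#' Calibrate the non-transplanted hazard to a chosen crossing size
#'
#' Inverse of [crossing_size()] (with `alpha1` fixed): the rate `delta1` for
#' which the two hazards cross exactly at `s_star`,
#' \deqn{\delta_1 = -\log\!\big(1 - \delta_2 s^*/(\alpha_0(\alpha_1-1))\big)/s^*.}
#' Errors when no such `delta1` exists (the transplanted hazard at `s_star`
#' already exceeds the non-transplanted ceiling).
#'
#' @param s_star Desired crossing size, cm, strictly positive.
#' @param scn An [hcc_scenario()] supplying `alpha0`, `alpha1`, `delta2`.
#' @return `delta1`, per cm.
#' @examples
#' calibrate_delta1(7, hcc_scenario())  # log(8)/7 = 0.2970631
#' @export
calibrate_delta1 <- function(s_star, scn) {
  stopifnot(is.numeric(s_star), length(s_star) == 1L, s_star > 0)
  arg <- 1 - scn$delta2 * s_star / (scn$alpha0 * (scn$alpha1 - 1))
  if (arg <= 0)
    stop("no feasible delta1: requested crossing size is beyond the reach ",
         "of the saturating hazard", call. = FALSE)
  -log(arg) / s_star
}

check_sizes <- function(s) {
  if (!is.numeric(s) || any(is.na(s)))
    stop("tumor sizes must be numeric and non-missing", call. = FALSE)
  if (any(s < 0))
    stop("tumor sizes must be non-negative (cm)", call. = FALSE)
  invisible(s)
}
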