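#' Transplanted and non-transplanted size densities under a policy
#'
#' Splits the population size density \eqn{p(s) = \lambda e^{-\lambda s}}
#' into the transplanted part \eqn{x(s)} and its complement \eqn{y(s)}.
#' Below the policy threshold `s0` a fraction `g(s) * F/N` of each size class
#' is transplanted, so \eqn{x(s) = g(s)(F/N)p(s)} and \eqn{y(s) = p(s) -
#' x(s)}; above the threshold nobody is transplanted. The two always add back
#' to `p(s)`.
#'
#' @param s Tumor size(s), cm.
#' @param scn An [hcc_scenario()]; its `s0` and bias `g` define the policy.
#' @return A list with components `x` and `y`, densities per cm.
#' @examples
#' allocation_densities(2, hcc_scenario())
#' @export
allocation_densities <- function(s, scn) {
  check_sizes(s)
  p <- size_pdf(s, scn$lambda)
  gv <- bias_at(scn, s)
  if (any(gv < 0 | gv > 1))
    stop("bias g(s) must lie in [0, 1]", call. = FALSE)
  x <- ifelse(s <= scn$s0, gv * (scn$F / scn$N) * p, 0)
  list(x = x, y = p - x)
}

#' Threshold at which the graft supply is exactly exhausted
#'
#' The size cutoff `s_F` such that transplanting every patient with
#' `s <= s_F` uses all `F` grafts: `N * P(size <= s_F) = F`, i.e.
#' \eqn{s_F = -\log(1 - F/N)/\lambda}.
#'
#' @param scn An [hcc_scenario()].
#' @return `s_F` in cm.
#' @examples
#' full_utilization_threshold(hcc_scenario())  # 1.3516 cm
#' @export
full_utilization_threshold <- function(scn) {
  -log(1 - scn$F / scn$N) / scn$lambda
}

#' Allocation proportions under the Milan criteria
#'
#' The four-way split of the waiting list induced by a hard Milan size cutoff
#' `S_M`: transplanted / non-transplanted, below / above the cutoff, as
#' proportions of all `N` patients. Two regimes apply. When grafts are scarce
#' (`F < N * P(size <= S_M)`), every graft goes below the cutoff: a fraction
#' `F/N` of the population is transplanted there, nobody above. When grafts
#' exceed the sub-cutoff demand ("liver-rich"), the split follows the
#' proportional rule `F/N` applied across all sizes, so some transplants land
#' above the cutoff. The two regimes are distinct policies and the
#' transplanted split is deliberately not continuous across the boundary
#' `F = N * P(size <= S_M)`; the non-transplanted proportions and the
#' aggregate totals (`F/N` transplanted, `1 - F/N` not) are.
#'
#' @param scn An [hcc_scenario()].
#' @return A list of class `"milan_summary"`: `p_nt_below`, `p_t_below`,
#'   `p_nt_above`, `p_t_above` (proportions summing to 1) and `branch`
#'   (`"liver-scarce"` or `"liver-rich"`).
#' @examples
#' milan_summary(hcc_scenario())
#' @export
milan_summary <- function(scn) {
  N <- scn$N; F <- scn$F
  below <- size_cdf(scn$S_M, scn$lambda)   # 1 - exp(-lambda * S_M)
  above <- 1 - below
  if (F < N * below) {
    out <- list(p_nt_below = (N * below - F) / N,
                p_t_below  = F / N,
                p_nt_above = above,
                p_t_above  = 0,
                branch = "liver-scarce")
  } else {
    out <- list(p_nt_below = 0,
                p_t_below  = (F / N) * below,
                p_nt_above = 1 - F / N,
                p_t_above  = F * above / N,
                branch = "liver-rich")
  }
  class(out) <- "milan_summary"
  out
}

#' @export
print.milan_summary <- function(x, ...) {
  cat(sprintf("Milan allocation proportions (%s branch)\n", x$branch))
  m <- matrix(c(x$p_t_below, x$p_t_above, x$p_nt_below, x$p_nt_above),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("transplanted", "non-transplanted"),
                              c("below S_M", "above S_M")))
  print(round(m, 6))
  invisible(x)
}

#' Expected number of grafts consumed by a threshold policy
#'
#' Under the unbiased proportional policy, the expected number of grafts used
#' when transplanting up to size `s0` is `F * P(size <= s0) =
#' F * (1 - exp(-lambda * s0))` — a threshold beyond which few patients exist
#' leaves part of the supply idle.
#'
#' @param scn An [hcc_scenario()].
#' @param s0 Threshold in cm; defaults to the scenario's own.
#' @return Expected graft count (real-valued; the continuum model does not
#'   round).
#' @examples
#' grafts_used(hcc_scenario(), s0 = 10)  # 475.1 of 500
#' @export
grafts_used <- function(scn, s0 = scn$s0) {
  check_sizes(s0)
  scn$F * size_cdf(s0, scn$lambda)
}
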