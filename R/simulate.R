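#' Simulate an individual-based waiting-list cohort
#'
#' Stochastic counterpart of the deterministic model, used as an independent
#' check on the quadrature results. Each of the `N` patients draws a tumor
#' size from the exponential distribution; patients at or below the policy
#' threshold are transplanted independently with probability `g(s) * F/N`
#' (Bernoulli thinning, mirroring the continuum density `x(s)`); if the
#' realized transplant count exceeds the integer graft supply `F`, the excess
#' is revoked uniformly at random. Each patient then draws an exponential
#' death clock at the hazard matching their status, constant in time at fixed
#' size.
#'
#' @param object An [hcc_scenario()].
#' @param nsim Number of cohorts to generate.
#' @param seed Integer seed; the cohort is reproduced bit-for-bit when
#'   reused. `NULL` leaves the RNG state alone.
#' @param ... Unused.
#' @return For `nsim = 1` a data frame of class `"sim_cohort"` with columns
#'   `size_cm`, `transplanted`, `death_time_years`, and attributes `seed` and
#'   `params`; otherwise a list of such frames (each with its own child
#'   seed).
#' @examples
#' coh <- simulate(hcc_scenario(), seed = 1)
#' head(coh)
#' simulate_deaths(coh, T = 5)
#' @export
simulate.hcc_scenario <- function(object, nsim = 1, seed = NULL, ...) {
  stopifnot(nsim >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (nsim > 1) {
    seeds <- sample.int(.Machine$integer.max, nsim)
    return(lapply(seeds, function(s) simulate.hcc_scenario(object, 1, s)))
  }
  scn <- object
  N <- as.integer(round(scn$N))
  F <- as.integer(round(scn$F))
  sizes <- stats::rexp(N, rate = scn$lambda)
  p_tx <- ifelse(sizes <= scn$s0, bias_at(scn, sizes) * scn$F / scn$N, 0)
  tx <- stats::runif(N) < p_tx
  excess <- sum(tx) - F
  if (excess > 0) {                      # graft supply is integer and hard
    revoke <- sample(which(tx), excess)
    tx[revoke] <- FALSE
  }
  rate <- ifelse(tx, hazard_transplanted(sizes, scn),
                 hazard_nontransplanted(sizes, scn))
  death <- stats::rexp(N, rate = rate)
  out <- data.frame(size_cm = sizes, transplanted = tx,
                    death_time_years = death)
  attr(out, "seed") <- seed
  attr(out, "params") <- scenario_record(scn)
  class(out) <- c("sim_cohort", class(out))
  out
}

#' Count deaths in a simulated cohort by a time horizon
#'
#' @param cohort A cohort from [simulate.hcc_scenario()].
#' @param T Horizon in years.
#' @return Number of patients whose death clock rang at or before `T`.
#' @export
simulate_deaths <- function(cohort, T) {
  stopifnot(inherits(cohort, "sim_cohort"), T >= 0)
  sum(cohort$death_time_years <= T)
}

#' Monte-Carlo estimate of total mortality
#'
#' Mean and standard error of the death count at horizon `T` over
#' independent replicate cohorts, at a given threshold. Agrees with
#' [total_mortality()] to Monte-Carlo error; two runs with the same seed are
#' identical.
#'
#' @param scn An [hcc_scenario()].
#' @param s0 Threshold in cm; defaults to the scenario's own.
#' @param reps Number of replicate cohorts (at least 2).
#' @param seed Master seed; per-replicate child seeds are derived from it.
#' @return A list: `mean`, `se`, `reps`, `deaths` (per-replicate counts).
#' @examples
#' mc_mortality(hcc_scenario(), s0 = 7, reps = 20, seed = 1)$mean
#' @export
mc_mortality <- function(scn, s0 = scn$s0, reps = 100, seed = NULL) {
  stopifnot(reps >= 2)
  scn2 <- scn; scn2$s0 <- s0
  cohorts <- simulate.hcc_scenario(scn2, nsim = reps, seed = seed)
  deaths <- vapply(cohorts, simulate_deaths, 0L, T = scn$T)
  list(mean = mean(deaths),
       se = stats::sd(deaths) / sqrt(reps),
       reps = reps,
       deaths = deaths)
}

#' Fit an exponential distribution to observed tumor sizes
#'
#' Maximum-likelihood exponential fit: `lambda_hat = 1 / mean(sizes)`. The
#' 95% CI for the mean is the normal-approximation (Wald) interval
#' `mean * (1 +/- 1.96/sqrt(n))`, the exponential's coefficient of variation
#' being 1. `ci95_rounded_mean` repeats the computation with the mean first
#' rounded to one decimal, as size data are typically reported; both are
#' returned. Goodness of fit is the R-squared between binned relative
#' frequencies (density scale) and the fitted density at bin midpoints.
#'
#' @param sizes Strictly positive tumor sizes, cm (`n >= 2`).
#' @param bin_width Histogram bin width for the R-squared, cm (default 1).
#' @param bin_range Range covered by the bins (default `c(0, 12)`; extended
#'   if the data exceed it).
#' @return An object of class `"tumor_size_fit"`: `lambda_hat`, `mean_hat`,
#'   `ci95`, `ci95_rounded_mean`, `n`, `r_squared`.
#' @examples
#' set.seed(1)
#' fit_tumor_sizes(rexp(327, rate = 0.3))
#' @export
fit_tumor_sizes <- function(sizes, bin_width = 1, bin_range = c(0, 12)) {
  if (!is.numeric(sizes) || length(sizes) < 2L)
    stop("need at least two numeric tumor sizes", call. = FALSE)
  if (any(is.na(sizes)) || any(sizes <= 0))
    stop("tumor sizes must be positive and non-missing", call. = FALSE)
  n <- length(sizes)
  m <- mean(sizes)
  lam <- 1 / m
  half <- 1.96 / sqrt(n)
  m_r <- round(m, 1)
  breaks <- seq(bin_range[1], max(bin_range[2], ceiling(max(sizes))),
                by = bin_width)
  if (max(sizes) > max(breaks)) breaks <- c(breaks, max(sizes))
  h <- graphics::hist(sizes, breaks = breaks, plot = FALSE)
  obs <- h$density
  fitv <- stats::dexp(h$mids, rate = lam)
  r2 <- 1 - sum((obs - fitv)^2) / sum((obs - mean(obs))^2)
  structure(list(lambda_hat = lam, mean_hat = m,
                 ci95 = c(m * (1 - half), m * (1 + half)),
                 ci95_rounded_mean = c(m_r * (1 - half), m_r * (1 + half)),
                 n = n, r_squared = r2),
            class = "tumor_size_fit")
}

#' @export
print.tumor_size_fit <- function(x, ...) {
  cat("Exponential tumor-size fit\n")
  cat(sprintf("  n = %d, mean = %.3f cm, lambda = %.4f /cm\n",
              x$n, x$mean_hat, x$lambda_hat))
  cat(sprintf("  95%% CI for the mean: [%.2f, %.2f] cm ([%.2f, %.2f] from the rounded mean)\n",
              x$ci95[1], x$ci95[2],
              x$ci95_rounded_mean[1], x$ci95_rounded_mean[2]))
  cat(sprintf("  binned-density R^2 = %.3f\n", x$r_squared))
  invisible(x)
}
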