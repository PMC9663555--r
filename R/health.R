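## IER relative risk, attributable premature mortality with Monte Carlo
## uncertainty, and percentile CI summaries.

#' Integrated Exposure Response relative risk
#'
#' RR(chi) = 1 + alpha * (1 - exp(-beta * (chi - chi0)^delta)) for
#' chi > chi0, and 1 at or below the minimum-risk concentration chi0.
#' Continuous at chi0 and non-decreasing in chi; tends to 1 + alpha for
#' large chi. Vectorized over any argument.
#'
#' @param chi exposure in ug/m3 (>= 0).
#' @param alpha,beta,delta positive shape parameters.
#' @param chi0 minimum-risk concentration in ug/m3.
#' @return relative risk (>= 1).
#' @export
ier_rr <- function(chi, alpha, beta, delta, chi0) {
  if (any(chi < 0)) stop("exposure must be non-negative", call. = FALSE)
  assert_that(all(alpha > 0) && all(beta > 0) && all(delta > 0),
              "IER parameters must be positive")
  excess <- pmax(chi - chi0, 0)
  1 + alpha * (1 - exp(-beta * excess^delta))
}

#' Percentile summary of Monte Carlo draws
#'
#' Mean and central percentile interval (2.5th/97.5th for the default 95%
#' level) of a vector of per-draw values.
#'
#' @param x numeric vector of per-draw values.
#' @param level interval coverage (default 0.95).
#' @return list with `mean`, `ci_low`, `ci_high`.
#' @export
mc_summarize <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  q <- unname(quantile(x, probs = c(a, 1 - a), names = FALSE, type = 7))
  list(mean = mean(x), ci_low = q[1], ci_high = q[2])
}

# per-draw deaths for one cause; returns a vector over draws
cause_deaths_draws <- function(cause, chi, dchi, demo, draws, total_pop) {
  p <- draws$draws[[cause]]
  rr1 <- ier_rr(chi, p$alpha, p$beta, p$delta, p$chi0)
  rr0 <- ier_rr(pmax(chi - dchi, 0), p$alpha, p$beta, p$delta, p$chi0)
  shares <- demo$age_shares
  bmr <- demo$bmr[cause, ]
  if (cause %in% demo$age_weighted_causes) {
    # scale the excess risk by the age multiplier, then take the
    # attributable fraction age group by age group
    out <- numeric(length(rr1))
    for (a in seq_along(shares)) {
      m <- demo$age_rr_multiplier[a]
      r1 <- 1 + m * (rr1 - 1)
      r0 <- 1 + m * (rr0 - 1)
      af <- (r1 - r0) / r1
      out <- out + total_pop * shares[a] * bmr[a] * af
    }
    out
  } else {
    af <- (rr1 - rr0) / rr1
    sum(total_pop * shares * bmr) * af
  }
}

#' Premature deaths attributable to an exposure increment
#'
#' Converts a population-weighted exposure increment delta_chi_pw (the
#' burning-attributable share of the baseline) into cause- and
#' age-stratified premature deaths. Per draw and cause the attributable
#' fraction is (RR(chi) - RR(chi - delta_chi)) / RR(chi) evaluated at the
#' population-weighted baseline chi; deaths are baseline deaths times that
#' fraction, with age-specific excess-risk multipliers for IHD and
#' cerebrovascular disease. Mean and 95% percentile CI are taken over the
#' Monte Carlo draw set.
#'
#' @param delta_chi_pw attributable exposure increment, ug/m3 (>= 0, and
#'   no larger than the baseline).
#' @param pw_chi_base population-weighted baseline PM2.5, ug/m3 (all
#'   sources, burning included).
#' @param demo `demography_table`.
#' @param draws `ier_draws`.
#' @param total_pop exposed population count.
#' @param level CI coverage (default 0.95).
#' @return object of class `mortality_estimate`: `deaths_mean`,
#'   `deaths_ci_low`, `deaths_ci_high`, per-cause table `by_cause`, and the
#'   per-draw totals in `draws_total`.
#' @export
attributable_deaths <- function(delta_chi_pw, pw_chi_base, demo, draws,
                                total_pop, level = 0.95) {
  assert_that(delta_chi_pw >= 0, "delta_chi_pw must be >= 0")
  if (delta_chi_pw > pw_chi_base)
    stop("cannot attribute more exposure (", delta_chi_pw,
         ") than the baseline (", pw_chi_base, ")", call. = FALSE)
  per_cause <- lapply(demo$causes, cause_deaths_draws, chi = pw_chi_base,
                      dchi = delta_chi_pw, demo = demo, draws = draws,
                      total_pop = total_pop)
  names(per_cause) <- demo$causes
  total_draws <- Reduce(`+`, per_cause)
  s <- mc_summarize(total_draws, level)
  by_cause <- do.call(rbind, lapply(demo$causes, function(h) {
    cs <- mc_summarize(per_cause[[h]], level)
    data.frame(cause = h, deaths_mean = cs$mean,
               deaths_ci_low = cs$ci_low, deaths_ci_high = cs$ci_high)
  }))
  structure(list(deaths_mean = s$mean, deaths_ci_low = s$ci_low,
                 deaths_ci_high = s$ci_high, by_cause = by_cause,
                 draws_total = total_draws, draws_by_cause = per_cause,
                 level = level),
            class = "mortality_estimate")
}

#' @export
print.mortality_estimate <- function(x, ...) {
  cat(sprintf(
    "<mortality_estimate> %.0f premature deaths (%.0f%% CI: %.0f-%.0f)\n",
    x$deaths_mean, 100 * x$level, x$deaths_ci_low, x$deaths_ci_high))
  invisible(x)
}
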