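## VSL benefit transfer and monetization of attributable deaths.

#' Benefit-transferred Value of Statistical Life for a target year
#'
#' Per Monte Carlo draw, the US 1990 VSL (Weibull-distributed) is grown to
#' the target year with the US real-GDP-per-capita ratio raised to the
#' within-US income elasticity (0.7) and the GDP deflator ratio, then
#' transferred with the target/US PPP income ratio raised to the
#' cross-country income elasticity (1.5):
#' V_y = V_US1990 * (G_y/G_1990)^e1 * (D_y/D_1990) * R_y^e2.
#'
#' @param econ `econ_series`.
#' @param year target year (must be present in the series).
#' @param n_draws number of Monte Carlo draws.
#' @param seed integer seed.
#' @return object of class `vsl_estimate` with per-draw values (`draws`,
#'   USD), `vsl_mean`, `vsl_ci_low`, `vsl_ci_high`.
#' @export
vsl_transfer <- function(econ, year, n_draws = 1000L, seed = 1L) {
  s <- econ$series
  if (!(year %in% s$year))
    stop("year ", year, " is not in the economic series", call. = FALSE)
  base <- s[s$year == 1990L, ]
  tgt <- s[s$year == year, ]
  set.seed(sub_seed(seed, "vsl"))
  v_us_1990 <- rweibull(n_draws, shape = econ$vsl_us_1990_shape,
                        scale = econ$vsl_us_1990_scale)
  v <- v_us_1990 *
    (tgt$gdp_per_capita_us / base$gdp_per_capita_us)^econ$epsilon1 *
    (tgt$gdp_deflator / base$gdp_deflator) *
    tgt$ppp_ratio^econ$epsilon2
  sm <- mc_summarize(v)
  structure(list(year = year, draws = v, vsl_mean = sm$mean,
                 vsl_ci_low = sm$ci_low, vsl_ci_high = sm$ci_high),
            class = "vsl_estimate")
}

#' Monetized cost of attributable premature mortality
#'
#' Pairs mortality draw k with VSL draw k (one coherent Monte Carlo), takes
#' the per-draw product deaths x VSL, and summarizes with mean and
#' percentile CI.
#'
#' @param deaths_draws per-draw attributable deaths (e.g.
#'   `mortality_estimate$draws_total`).
#' @param vsl_draws per-draw VSL in USD (e.g. `vsl_estimate$draws`); must
#'   have the same length.
#' @param level CI coverage.
#' @return object of class `monetized_cost` with `cost_mean`,
#'   `cost_ci_low`, `cost_ci_high` (USD) and the per-draw products.
#' @export
monetize <- function(deaths_draws, vsl_draws, level = 0.95) {
  if (inherits(deaths_draws, "mortality_estimate"))
    deaths_draws <- deaths_draws$draws_total
  if (inherits(vsl_draws, "vsl_estimate")) vsl_draws <- vsl_draws$draws
  assert_that(length(deaths_draws) == length(vsl_draws),
              "death and VSL draw counts differ; draws are paired k-with-k")
  draws <- deaths_draws * vsl_draws
  sm <- mc_summarize(draws, level)
  structure(list(cost_mean = sm$mean, cost_ci_low = sm$ci_low,
                 cost_ci_high = sm$ci_high, draws = draws, level = level),
            class = "monetized_cost")
}
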