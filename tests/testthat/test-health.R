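test_that("IER relative risk has the right boundary, limit and hand value", {
  expect_equal(ier_rr(5, 1, 0.1, 1, 5), 1)       # at the minimum-risk level
  expect_equal(ier_rr(2, 1, 0.1, 1, 5), 1)       # below it
  expect_equal(ier_rr(15, 1, 0.1, 1, 5), 1 + (1 - exp(-1)))  # hand arithmetic
  expect_equal(ier_rr(1e7, 0.8, 0.05, 0.9, 4), 1 + 0.8, tolerance = 1e-9)
  # continuity at chi0
  expect_equal(ier_rr(5 + 1e-10, 1, 0.1, 1, 5), 1, tolerance = 1e-9)
  expect_error(ier_rr(-1, 1, 0.1, 1, 5), "non-negative")
  expect_error(ier_rr(10, -1, 0.1, 1, 5), "positive")
})

test_that("IER is non-decreasing in exposure for random parameter draws", {
  draws <- draw_ier_params(100, seed = 17)
  chi_grid <- seq(0, 300, by = 1.5)
  for (h in names(draws$draws)) {
    p <- draws$draws[[h]]
    for (k in seq_len(20)) {   # 20 draws per cause x 5 causes = 100
      rr <- ier_rr(chi_grid, p$alpha[k], p$beta[k], p$delta[k], p$chi0[k])
      expect_true(all(diff(rr) >= -1e-12))
      expect_true(all(rr >= 1))
    }
  }
})

test_that("mc_summarize matches a sort-based oracle and degenerates cleanly", {
  s <- mc_summarize(rep(3.2, 50))
  expect_equal(unlist(s), c(mean = 3.2, ci_low = 3.2, ci_high = 3.2))

  set.seed(33)
  x <- rnorm(1000, 10, 2)
  s <- mc_summarize(x)
  # independent interpolation oracle (type-7 definition written out)
  sorted <- sort(x)
  q_oracle <- function(p) {
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    sorted[lo] + (h - lo) * (sorted[lo + 1] - sorted[lo])
  }
  expect_equal(s$ci_low, q_oracle(0.025), tolerance = 1e-12)
  expect_equal(s$ci_high, q_oracle(0.975), tolerance = 1e-12)
  expect_equal(s$mean, sum(x) / length(x))
})

test_that("the 95% percentile interval is calibrated on a known distribution", {
  # coverage of a fresh draw from the same distribution: the 2.5th-97.5th
  # percentile band of 1000 draws should contain it ~95% of the time. (The
  # interval contains the true mean essentially always, which would be a
  # vacuous check.)
  set.seed(101)
  hits <- 0L
  for (r in 1:500) {
    x <- rnorm(1000, 5, 3)
    s <- mc_summarize(x)
    fresh <- rnorm(1, 5, 3)
    if (fresh >= s$ci_low && fresh <= s$ci_high) hits <- hits + 1L
  }
  expect_gte(hits / 500, 0.92)
  expect_lte(hits / 500, 0.98)
})

test_that("attributable deaths vanish without exposure or risk gradient", {
  demo <- make_demography(seed = 1)
  draws <- draw_ier_params(200, seed = 1)
  z <- attributable_deaths(0, 60, demo, draws, 1e7)
  expect_equal(z$deaths_mean, 0)
  expect_equal(c(z$deaths_ci_low, z$deaths_ci_high), c(0, 0))

  flat <- hand_ier_draws(alpha = 1e-12, beta = 0.05, delta = 0.8, chi0 = 4)
  f <- attributable_deaths(5, 60, demo, flat, 1e7)
  expect_lt(f$deaths_mean, 1e-6)

  expect_error(attributable_deaths(70, 60, demo, draws, 1e7), "baseline")
  expect_error(attributable_deaths(-1, 60, demo, draws, 1e7), ">= 0")
})

test_that("a single hand-set draw matches a spreadsheet-style computation", {
  demo <- make_demography(seed = 2)
  draws <- hand_ier_draws(alpha = 1.2, beta = 0.03, delta = 0.9, chi0 = 4)
  pop <- 2e7; chi <- 70; dchi <- 6
  est <- attributable_deaths(dchi, chi, demo, draws, pop)

  # independent arithmetic, cause by cause and age by age
  rr <- function(x) 1 + 1.2 * (1 - exp(-0.03 * (x - 4)^0.9))
  expected <- 0
  for (h in demo$causes) {
    if (h %in% demo$age_weighted_causes) {
      for (a in seq_along(demo$ages)) {
        m <- demo$age_rr_multiplier[[a]]
        r1 <- 1 + m * (rr(chi) - 1); r0 <- 1 + m * (rr(chi - dchi) - 1)
        expected <- expected + pop * demo$age_shares[[a]] *
          demo$bmr[h, a] * (r1 - r0) / r1
      }
    } else {
      af <- (rr(chi) - rr(chi - dchi)) / rr(chi)
      for (a in seq_along(demo$ages))
        expected <- expected + pop * demo$age_shares[[a]] * demo$bmr[h, a] * af
    }
  }
  expect_equal(est$deaths_mean, expected, tolerance = 1e-12)
  # single draw: degenerate CI
  expect_equal(est$deaths_ci_low, expected, tolerance = 1e-12)
})

test_that("deaths are monotone in the increment, linear for small ones, and
           additive over causes", {
  demo <- make_demography(seed = 3)
  draws <- draw_ier_params(100, seed = 3)
  chi <- 65; pop <- 3e7
  d1 <- attributable_deaths(1, chi, demo, draws, pop)$deaths_mean
  d3 <- attributable_deaths(3, chi, demo, draws, pop)$deaths_mean
  d6 <- attributable_deaths(6, chi, demo, draws, pop)$deaths_mean
  expect_true(d1 <= d3 && d3 <= d6)

  # small-increment linearity: deaths(eps) ~ eps * deaths'(0) within 1%
  eps <- 1e-3 * chi
  de <- attributable_deaths(eps, chi, demo, draws, pop)$deaths_mean
  slope <- attributable_deaths(2 * eps, chi, demo, draws, pop)$deaths_mean / 2
  expect_equal(de, slope, tolerance = 0.01)

  est <- attributable_deaths(6, chi, demo, draws, pop)
  expect_equal(sum(est$by_cause$deaths_mean), est$deaths_mean,
               tolerance = 1e-12)
  expect_equal(Reduce(`+`, est$draws_by_cause), est$draws_total)
  expect_true(est$deaths_ci_low <= est$deaths_mean &&
                est$deaths_mean <= est$deaths_ci_high)
})
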